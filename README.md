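# GCtetrads

Aureolic-acid antibiotics — olivomycin A (OA), mithramycin, chromomycin A3 —
bind as dimers in the DNA minor groove at short runs of G/C base pairs and
interfere with transcription. The OA binding-site consensus is the
degenerate tetrad **SGSS** (S = G or C), whose reverse complement is
**SSCS**; the guanine at the fixed position is *obligate*: its minor-groove
amino group is required for drug binding, so substituting that G with A
(G→A on its strand) abrogates the site.

`GCtetrads` implements the computational workflow of a promoter study of
such ligands, for molecular biologists who want to

- **map putative OA sites**: scan sequences for SGSS/SSCS (and arbitrary
  IUPAC patterns) on both strands, merge overlapping matches into discrete
  sites, and export BED/TSV (`scanPattern`, `scanBothStrands`,
  `scanTetrads`, `mergeSites`, `exportSitesBed`);
- **build promoter maps**: strand-aware ±W windows around TSSs (default
  W = 2500 bp), TSS-relative *d(SGSS)* coordinates, overlays of
  transcription-factor ChIP-seq peaks, and factor classification as
  `ubiquitous` / `sensitive_restricted` / `absent` (`makeWindows`,
  `toRelative`, `overlayPeaks`, `classifyFactors`);
- **design tetrad-abrogated mutants** (the CMVwt→CMVmut procedure):
  leftmost-first greedy G→A / C→T substitution of obligate guanines with
  rescan to fixpoint, protected intervals (e.g. an MluI cloning site) left
  intact, and an independent plan audit (`designMutant`, `verifyPlan`);
- **quantify qPCR and ChIP-qPCR time courses**: ΔΔCt relative expression
  with a reference-gene normalizer (fold change = 2^(−ΔΔCt)) and
  dilution-adjusted percent-of-input ChIP enrichment with 0 h taken as
  100% (`deltaDeltaCt`, `percentInput`, `chipPercentInput`,
  `normalizeToT0`);
- **classify transcriptional sensitivity** of genes into groups
  I (highly sensitive: two-fold drop within 1–6 h, sustained to 12 h),
  II (averagely sensitive: ~50% down by 12 h) and III (weakly sensitive)
  (`classifyResponse`, `classifyCohort`);
- **simulate all of the above with planted ground truth** under a single
  seed (`simConfig`, `simPromoters`, `simCtTables`, `simPeaks`,
  `simStudy`).

Sequence and interval work is built on Bioconductor containers: sites and
peaks are `GRanges`, sequences are `Biostrings` objects, BED goes through
`rtracklayer`.

## Worked example

The package ships a **synthetic stand-in** of the minimal CMV promoter
construct (`inst/extdata/cmv_minimal_promoter_synthetic.fa`; see the
vignette for what it emulates). The cmvF/cmvR primer pair delimits a
144 bp fragment, and the census of merged SGSS/SSCS tetrads outside the
protected MluI cloning site yields the five sites that are mutagenized:

```r
library(GCtetrads)

tmpl <- cmvSyntheticPromoter()
p <- cmvPrimers()
pcrProduct(tmpl, p["cmvF"], p["cmvR"])$length
#> [1] 144

merged <- mergeSites(scanTetrads(tmpl))
prot <- mluIProtected()
sum(!IRanges::overlapsAny(IRanges::ranges(merged), prot))
#> [1] 5

res <- designMutant(tmpl, protected = prot)
res$plan
#> MutagenesisPlan: 5 substitution(s), 1 protected interval(s),
#>   1 residual site(s), 0 conflict(s), 5 iteration(s)
#>   pos 60: G>A (+, SGSS)
#>   pos 80: C>T (-, SSCS)
#>   pos 98: G>A (+, SGSS)
#>   pos 117: G>A (+, SGSS)
#>   pos 137: C>T (-, SSCS)
verifyPlan(tmpl[[1]], res$mutant, res$plan)$ok
#> [1] TRUE
```

Each substitution hits the obligate guanine of one tetrad (C>T rows are
reverse-strand guanines); the one residual site is the protected CGCG
inside the MluI site. A ΔΔCt example:

```r
ct <- data.frame(target = rep(c("MYC", "RPLP0"), each = 2),
                 condition = rep(c("untreated", "OA"), 2),
                 time_h = rep(c(0, 3), 2), replicate = 1,
                 ct = c(20, 23, 15, 15))
deltaDeltaCt(ct, "MYC")[, c("condition", "ddct", "fold_change")]
#>   condition ddct fold_change
#> 1 untreated    0       1.000
#> 2        OA    3       0.125
```

Three extra cycles of the target at constant normalizer is ΔΔCt = 3,
i.e. 2^−3 = 12.5% of the untreated level.

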