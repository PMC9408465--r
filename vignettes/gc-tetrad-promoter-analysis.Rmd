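---
title: "Mapping GC tetrads and quantifying transcriptional inhibition by aureolic-acid DNA ligands"
author: "GCtetrads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GC tetrads and quantifying transcriptional inhibition by aureolic-acid DNA ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GCtetrads)
```

## The biological problem

Aureolic-acid antibiotics (olivomycin A, mithramycin, chromomycin A3) are
minor-groove DNA ligands with a strong preference for G/C-rich sequence.
Olivomycin A (OA) binds as a dimer across four consecutive G/C base pairs;
the binding-competent consensus is the degenerate tetrad **SGSS**
(S = G or C), read on either strand — its reverse complement on the
forward strand is **SSCS**. One guanine in the tetrad is *obligate*: its
2-amino group in the minor groove contacts the drug's aglycon, so removing
that guanine (G→A, which in the minor groove replaces the amino group with
a hydrogen) abrogates binding without otherwise rearranging the site.

A promoter study of such a ligand needs five computational pieces, which
this package provides as composable functions: a degenerate-motif scanner,
a TSS-centred promoter atlas with transcription-factor peak overlays, a
mutant-promoter designer, ΔΔCt/percent-of-input quantification of
qPCR/ChIP-qPCR time courses, and a sensitivity classifier for gene
response profiles. A seeded generator produces synthetic inputs with
planted ground truth for every stage, which is how the package tests
itself end to end.

## Scanning for tetrad sites

`scanPattern()` matches a degenerate IUPAC pattern position-by-position
against the forward strand; all overlapping occurrences are reported, in
ascending start order. Coordinates are 0-based half-open internally at I/O
boundaries (BED stays 0-based half-open) and 1-based closed inside R,
following the `GRanges` convention of the containers the results live in.

Three decisions here are worth making explicit:

* **Ambiguity codes in the subject never match.** An `N` (or any
  non-A/C/G/T base) in the scanned sequence fails every pattern position,
  including pattern `N`. This is conservative site calling: an uncertain
  base is never evidence for a binding site.
* **Raw matches and merged sites are different views.** Overlapping
  matches are all reported; `mergeSites()` is a separate, explicit step
  that unions overlapping or bookended intervals into discrete regions
  (idempotent, coverage-preserving, never across sequences). Counting
  conventions differ between the two views, so both stay available.
* **The default "OA site" set is `{SGSS, SSCS}` on the forward strand**,
  which is exactly SGSS on both strands: `reverseComplement(SGSS) = SSCS`,
  and `scanBothStrands()` asserts this duality by construction (a
  reverse-strand SGSS site is a forward-strand SSCS match at the same
  interval).

```{r scan}
scanTetrads("TTGGCGTTCCCGTT")
mergeSites(scanPattern("GGGGG", "SGSS"))
```

The test suite holds the scanner against two independent references: a
naive position-by-position brute-force matcher (1000 random sequences per
run) and `Biostrings::matchPattern(fixed = FALSE)`.

## Promoter windows and the d(SGSS) axis

`makeWindows()` builds `[tss − W, tss + W)` windows (default
`W = 2500` bp, the span used for promoter tetrad/peak mapping);
`toRelative()` converts genomic intervals to TSS-relative,
transcription-oriented coordinates — upstream is negative, and the axis of
a minus-strand gene is mirrored so that applying the mirror twice returns
the original interval (a property the tests exercise). Sites wholly
outside ±W are dropped, partial overlaps are clipped, so every emitted
relative site satisfies `−W ≤ rel_start < rel_end ≤ +W`.

Peak overlap is the simplest defensible reading of "in the vicinity of the
TSS": **≥ 1 bp intersection with the window under half-open semantics**
(an abutting peak is absent). `classifyFactors()` then applies the
dichotomy observed for promoter-bound factors:

* `absent` — no peak in any analyzed gene's window;
* `sensitive_restricted` — present in ≥ 1 gene of groups I∪II and in no
  group III gene;
* `ubiquitous` — present in a *majority* of genes including ≥ 1 group III
  gene. "Majority" has no canonical definition here; the default threshold is
  50% and configurable;
* `other` — anything else, reported as such rather than forced into a
  category.

## Designing tetrad-abrogated mutants

`designMutant()` converts a wild-type sequence into its binding-dead
variant: substitute the obligate guanine of each unprotected site (SGSS:
pattern position 2, G→A; SSCS: pattern position 3, C→T — the same edit on
the other strand), leave protected intervals (cloning sites) untouched.
The experimental procedure defines *what* is substituted, not an
algorithm for choosing the edits, so the algorithm is this package's choice:

* **leftmost-first greedy with rescan to fixpoint.** Deterministic
  (ascending start, then pattern order), and safe: every edit replaces a
  G/C with A/T, so no new all-G/C tetrad can appear and each round
  strictly reduces the G/C count — convergence is guaranteed and enforced
  with an iteration cap.
* **Conflicts are reported, never silently skipped.** A site whose
  obligate position lies inside a protected interval while the site is
  not fully protected cannot be abrogated under the G→A rule; it is
  returned in the plan's `conflicts` slot.
* **Minimality is not pursued.** The greedy can spend more substitutions
  than the number of merged site regions: overlapping matches three
  offsets apart share only one base, and their obligate positions are
  disjoint, so some clusters provably need two or more edits (e.g.
  `CGCCGCC`), and the leftmost rule itself is not always the
  edit-count-optimal choice within a cluster (in `GGGGGG`, editing the
  middle match's obligate G would clear all three matches at once). The
  audit trail, not optimality, is the design goal: `verifyPlan()`
  independently re-derives the sequence diff, checks every substitution's
  chemistry and protection, rescans the mutant, and demands that every
  surviving site be either a declared residual (inside protection) or a
  declared conflict.

```{r mutant}
res <- designMutant("TGGGGTTTCCCGT")
as.character(res$mutant)
substitutions(res$plan)
```

## ΔΔCt and percent-of-input quantification

Relative expression follows the standard ΔΔCt scheme with a reference-gene
normalizer (default `RPLP0`) and the untreated 0 h sample as reference:
ΔCt = mean Ct(target) − mean Ct(normalizer) per condition,
ΔΔCt = ΔCt(condition) − ΔCt(reference), fold change = `E^(−ΔΔCt)`.
Numerical choices:

* **Replicates are averaged on the Ct scale** (standard practice; the
  averaging scale is not stated in most protocols). Fewer than 3
  replicates triggers a warning; a single replicate yields `sd_log2 = NA`
  rather than a fabricated error bar.
* **SDs propagate in quadrature on the log2 scale** from the replicate
  variances of the four means entering ΔΔCt (the reference's variance
  contributes to every non-reference condition).
* **Amplification efficiency defaults to 2.0** (one cycle = one two-fold
  change) and is a configuration knob; without standard curves there is
  nothing better to assume.

ChIP enrichment is percent of input with explicit dilution adjustment:
`%input = 100 × 2^(Ct_input − log2(1/f) − Ct_IP)` where `f` is the
fraction of chromatin used as input. **`f` has no default** — it is a
required argument, because silently assuming a dilution factor is the one
way this quantity goes wrong unnoticed. `normalizeToT0()` rescales a
series so the untreated 0 h point reads exactly 100, the convention for
plotting enrichment dynamics.

A chain-consistency property pins the algebra: with a constant normalizer,
re-referencing is multiplicative,
`FC(A→C) = FC(A→B) × FC(B→C)` to floating tolerance.

## Sensitivity groups I/II/III

Gene time courses (fold change at 1, 3, 6, 12 h) are classified by bands,
not hypothesis tests — this kind of grouping is descriptive, and error bars at single time points are too few for
honest testing:

* **Group I** — fold change ≤ 0.5 at some t* ∈ {1, 3, 6} h *and*
  non-increasing from t* through 12 h. "Continued to decrease" needs a
  tolerance; the default allows a multiplicative wobble of τ = 1.1
  between consecutive points.
* **Group II** — not I, and fold change at 12 h ≤ 0.55. The 0.55 band
  operationalizes "decreased by ~50%".
* **Group III** — every |log2 FC| ≤ log2(1.5) ("changed
  insignificantly").
* A series matching none of the rules is resolved to the nearer of II/III
  by log2-scale distance, and the trace records the ambiguity. Every call
  carries a trace naming the rule and triggering time point, so a call is
  reproducible from its inputs by inspection.

All bands are configurable (`responseThresholds()`); the defaults are
documented interpretations of qualitative categories, not measured
constants. Group I calls are monotone: scaling a group-I series further
down never changes its call.

## The synthetic-data generator

`simConfig()` fixes the study conditions once; a single integer seed
drives every generator through its own derived stream (fixed offsets from
the master seed), so outputs are byte-identical under a seed and adding a
generator never perturbs the others. Defaults emulate the shape of the
real experiment:

* **Cohort**: 10 genes split 4/4/2 across groups I/II/III (the size and
  split of the analyzed gene set).
* **Promoters**: per-gene contigs of length 2W with the TSS at the
  centre; background bases i.i.d. at GC fraction 0.5; five exact tetrad
  words planted per promoter. Background positions are resampled until no
  accidental SGSS/SSCS match overlaps a ±4 bp guard band around a planted
  site, so recall accounting against the truth set is unambiguous
  (accidental sites far from planted ones are allowed — they are honest
  background).
* **Expression**: Ct = baseline − log2(expression) + N(0, σ) per
  replicate, σ = 0.2 cycles, triplicates, with an independent normalizer
  triplicate per gene plate. Planted log2 fold-change templates per group
  (I: −1.3/−2.0/−2.7/−3.4 at 1/3/6/12 h, forced non-increasing after
  per-gene jitter of SD 0.08; II: −0.15/−0.35/−0.55/−1.2;
  III: within ±0.15) are chosen so the *noiseless* trajectory always
  satisfies its own group rule with margin; with σ = 0.2 the ΔΔCt noise
  SD is 2σ/√3 ≈ 0.23 on the log2 scale, which predicts the observed
  ≈ 97% group recovery and log2-FC RMSE ≈ 0.22–0.24.
* **ChIP**: planted percent-of-input trajectories per antibody and group
  (RNAPII falling on sensitive genes, H3 rising, flat for group III),
  encoded through the same Ct model with input fraction 0.1.
* **Peaks**: 14 factors, 7 planted `ubiquitous` (peaks in ≥ 50% of
  windows including a group III gene) and 7 `sensitive_restricted`
  (peaks only in group I/II windows), mirroring the dichotomy described above.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: amplification-efficiency drift between
amplicons, inter-plate batch effects, biological (as opposed to
technical) replicate dispersion, sequence composition beyond i.i.d.
background (CpG islands, repeats), peak-caller artifacts, and any
chromatin-level coupling between tetrad binding and the measured ChIP
signals. Recovery rates on synthetic data are upper bounds for real data.

```{r sim}
cfg <- simConfig(seed = 1, nGenes = 4, geneIds = paste0("g", 1:4),
                 groups = c("I", "II", "III", "I"), halfWidth = 300)
sim <- simStudy(cfg)
sim$promoters$truth[1:3]
```

## The shipped reference sequence is synthetic

The worked examples use
`inst/extdata/cmv_minimal_promoter_synthetic.fa`, a **constructed
stand-in** for a minimal CMV promoter construct (no real vector
sequence is redistributed here). It reproduces the construct's
structural facts exactly: the cmvF/cmvR primer pair delimits a
144 bp core; the forward primer carries the MluI cloning site whose
internal CGCG tetrad is protected during mutagenesis; and five isolated
SGSS/SSCS tetrads sit between the primers on an A/T background, so the
census of merged, unprotected tetrads is 5 and the designed mutant makes
exactly five obligate-guanine substitutions. Numbers derived from this
sequence test the pipeline's mechanics on a faithful structure, not any
real promoter's base composition.

## Problem sizes and runtime

The test suite and the acceptance script size their simulations to run
comfortably on a laptop: 1000 random sequences (length ≤ 200) for the
scanner-vs-oracle and mutant-design audits, 200 genes for fold-change
error measurement, 500 genes for classifier recovery, 14 factors for
association recovery. These sizes give binomial/normal margins well beyond
the asserted thresholds (e.g. recovery ≈ 97% against a 95% bound with
n = 500).

## Known limitations

* No affinity or kinetics model: a tetrad is a binary site, though real
  OA–DNA complexes differ in dissociation rate by context.
* The mutant designer is sound but not edit-count-optimal (see above);
  global minimization (e.g. set cover over obligate positions) was
  deliberately not pursued.
* Factor classification treats peak files as ground truth; no peak
  calling, no download client.
* ΔΔCt assumes a single efficiency for all amplicons; no melt-curve QC or
  multi-plate calibration.
* Biological vs technical replicate levels are reported as given in the
  input table; the package does not infer the design.
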