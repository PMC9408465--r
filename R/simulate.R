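#' @importFrom stats rnorm runif
NULL

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the seeded synthetic-data generator. The defaults
#' reproduce the study conditions the pipeline is meant for: a ten-gene
#' cohort split 4/4/2 into sensitivity groups I/II/III, promoter windows
#' of half-width 2500 bp, five planted GC tetrads per promoter on a
#' GC-balanced background, triplicate qPCR/ChIP reactions with Gaussian Ct
#' noise of SD 0.2 cycles, and fourteen transcription factors split evenly
#' into ubiquitous and sensitive-restricted binders.
#'
#' A single integer seed fixes every output byte-identically; each
#' generator draws from its own derived stream (fixed offsets from the
#' seed), so adding one generator never perturbs another.
#'
#' @param seed Single integer master seed.
#' @param nGenes Number of genes.
#' @param geneIds Gene names; defaults to the ten-gene study cohort.
#' @param groups Sensitivity group labels (`I`/`II`/`III`) per gene.
#' @param halfWidth Promoter window half-width W (bp).
#' @param gcFraction Background GC fraction in `[0, 1]`.
#' @param tetradsPerGene Planted tetrads per promoter (ignored for genes
#'   listed in `tetradOffsets`).
#' @param tetradOffsets Optional named list of TSS-relative 0-based start
#'   offsets of planted tetrads per gene (each in `[-W, W - 4]`).
#' @param guardBand Guard band (bp) around planted sites kept free of
#'   accidental matches, for unambiguous recall accounting.
#' @param timesH Treated time points (h) of the expression time course.
#' @param trajectories Named list of per-group planted log2 fold-change
#'   templates, one value per element of `timesH`.
#' @param jitterSd SD of per-gene, per-time jitter added to the planted
#'   log2 trajectories (the jittered values are the recorded truth).
#' @param ctSigma Gaussian Ct noise SD (cycles).
#' @param replicates Technical replicates per reaction.
#' @param baselineCt,normalizerCt Mean Ct of the target at reference and
#'   of the normalizer gene.
#' @param inputFraction Fraction of chromatin used as ChIP input.
#' @param inputBaseCt Mean undiluted-equivalent input Ct.
#' @param chipTrajectories Named list (per antibody) of named lists (per
#'   group) of planted percent-of-input values at `c(0, timesH)`.
#' @param factorLabels Named character vector mapping factor names to
#'   planted association labels (`ubiquitous`, `sensitive_restricted`,
#'   `absent`).
#' @param peakWidth Mean simulated peak width (bp).
#' @return Validated configuration list (class `"SimConfig"`).
#' @seealso [simPromoters()], [simCtTables()], [simPeaks()], [simStudy()]
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 10L,
                      geneIds = NULL,
                      groups = NULL,
                      halfWidth = 2500L,
                      gcFraction = 0.5,
                      tetradsPerGene = 5L,
                      tetradOffsets = NULL,
                      guardBand = 4L,
                      timesH = c(1, 3, 6, 12),
                      trajectories = list(
                          I = c(-1.3, -2.0, -2.7, -3.4),
                          II = c(-0.15, -0.35, -0.55, -1.2),
                          III = c(0.05, -0.05, 0.1, -0.1)),
                      jitterSd = 0.08,
                      ctSigma = 0.2,
                      replicates = 3L,
                      baselineCt = 20,
                      normalizerCt = 15,
                      inputFraction = 0.1,
                      inputBaseCt = 24,
                      chipTrajectories = list(
                          RNAPII = list(I = c(4, 2.8, 2.0, 1.4, 0.9),
                                        II = c(4, 3.6, 3.2, 2.6, 1.9),
                                        III = c(4, 4.1, 3.9, 4.0, 4.0)),
                          H3 = list(I = c(2, 2.2, 2.6, 3.1, 3.6),
                                    II = c(2, 2.1, 2.3, 2.6, 3.0),
                                    III = c(2, 2.0, 2.1, 2.0, 2.0))),
                      factorLabels = c(
                          Max = "ubiquitous", Sp1 = "ubiquitous",
                          CTCF = "ubiquitous", YY1 = "ubiquitous",
                          TCF7L2 = "ubiquitous", ZBTB33 = "ubiquitous",
                          FOSL1 = "ubiquitous",
                          JUND = "sensitive_restricted",
                          CEBPB = "sensitive_restricted",
                          EGR1 = "sensitive_restricted",
                          USF1 = "sensitive_restricted",
                          ATF3 = "sensitive_restricted",
                          SRF = "sensitive_restricted",
                          TEAD4 = "sensitive_restricted"),
                      peakWidth = 300L) {
    if (is.null(geneIds))
        geneIds <- if (nGenes == 10L)
            c("SLC38A2", "PHLDA1", "MYC", "TRIB3", "ETS2", "LHX2",
              "NFKBIA", "CDKN1A", "ARL6IP1", "TMEM123")
        else sprintf("gene%03d", seq_len(nGenes))
    if (is.null(groups))
        groups <- if (nGenes == 10L)
            rep(c("I", "II", "III"), c(4L, 4L, 2L))
        else rep_len(c("I", "II", "III"), nGenes)
    stopifnot(length(seed) == 1L, is.finite(seed),
              abs(seed) < .Machine$integer.max,
              nGenes >= 0L, length(geneIds) == nGenes,
              length(groups) == nGenes,
              all(groups %in% c("I", "II", "III")),
              halfWidth > 0, gcFraction >= 0, gcFraction <= 1,
              tetradsPerGene >= 0, guardBand >= 0,
              replicates >= 1L,
              inputFraction > 0, inputFraction <= 1)
    if (ctSigma < 0)
        stop("'ctSigma' must be non-negative")
    for (g in names(trajectories))
        if (length(trajectories[[g]]) != length(timesH))
            stop("trajectory for group ", g,
                 " must have one value per time point")
    if (!is.null(tetradOffsets)) {
        for (g in names(tetradOffsets)) {
            off <- tetradOffsets[[g]]
            if (any(off < -halfWidth | off + 4 > halfWidth))
                stop("infeasible planted tetrad offset for gene ", g,
                     " (pattern does not fit inside the window)")
        }
    }
    structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                   geneIds = geneIds, groups = groups,
                   halfWidth = as.integer(halfWidth),
                   gcFraction = gcFraction,
                   tetradsPerGene = as.integer(tetradsPerGene),
                   tetradOffsets = tetradOffsets,
                   guardBand = as.integer(guardBand),
                   timesH = timesH, trajectories = trajectories,
                   jitterSd = jitterSd, ctSigma = ctSigma,
                   replicates = as.integer(replicates),
                   baselineCt = baselineCt, normalizerCt = normalizerCt,
                   inputFraction = inputFraction,
                   inputBaseCt = inputBaseCt,
                   chipTrajectories = chipTrajectories,
                   factorLabels = factorLabels,
                   peakWidth = as.integer(peakWidth)),
              class = "SimConfig")
}

.simBase <- function(n, gc) {
    sample(c("G", "C", "A", "T"), n, replace = TRUE,
           prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# A random concrete tetrad word: SGSS (obligate G at position 2) or its
# reverse complement SSCS (obligate C at position 3).
.simTetradWord <- function() {
    type <- sample(c("SGSS", "SSCS"), 1L)
    s <- function(k) sample(c("G", "C"), k, replace = TRUE)
    w <- if (type == "SGSS") c(s(1), "G", s(2)) else c(s(2), "C", s(1))
    list(type = type, word = w)
}

#' Simulate promoter sequences with planted GC tetrads
#'
#' Generates one promoter window per gene (its own contig, length 2W,
#' TSS at the centre) with background bases drawn i.i.d. at the configured
#' GC fraction and exact tetrad words planted at known TSS-relative
#' offsets. Background positions are resampled until no accidental
#' SGSS/SSCS match overlaps a guard band around any planted site, so
#' scanner recall against the truth set is unambiguous.
#'
#' @param config A [simConfig()].
#' @return List with `sequences` (named [Biostrings::DNAStringSet]),
#'   `truth` (`GRanges` of planted sites with `pattern_id` and
#'   TSS-relative `rel_start`), and `anchors` ([geneAnchors()] on the
#'   per-gene contigs, TSS at W, strand `+`).
#' @export
simPromoters <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 101L)
    W <- config$halfWidth
    L <- 2L * W
    seqs <- character(config$nGenes)
    truthRows <- list()
    for (gi in seq_len(config$nGenes)) {
        g <- config$geneIds[gi]
        off <- config$tetradOffsets[[g]]
        if (is.null(off) && config$tetradsPerGene > 0L) {
            gap <- 2L * config$guardBand + 8L
            for (try in 1:200) {
                off <- sort(sample(seq(-W + 10L, W - 14L),
                                   config$tetradsPerGene))
                if (config$tetradsPerGene < 2L ||
                    min(diff(off)) >= gap)
                    break
                off <- NULL
            }
            if (is.null(off))
                stop("could not place ", config$tetradsPerGene,
                     " non-overlapping tetrads for gene ", g)
        }
        off <- sort(off %||% integer(0))
        ch <- .simBase(L, config$gcFraction)
        words <- lapply(seq_along(off), function(i) .simTetradWord())
        plantCover <- rep(FALSE, L)
        for (i in seq_along(off)) {
            idx <- (W + off[i] + 1L):(W + off[i] + 4L)
            ch[idx] <- words[[i]]$word
            plantCover[idx] <- TRUE
        }
        # guard-band cleanup: resample background bases of accidental
        # sites that encroach on a planted site's guard band
        plantKey <- paste(W + off + 1L, W + off + 4L)
        guard <- IRanges(start = pmax(W + off + 1L - config$guardBand, 1L),
                         end = pmin(W + off + 4L + config$guardBand, L))
        for (round in 1:100) {
            hits <- scanTetrads(paste(ch, collapse = ""), seqId = "w")
            acc <- hits[!paste(start(hits), end(hits)) %in% plantKey]
            bad <- acc[IRanges::overlapsAny(ranges(acc), guard)]
            if (!length(bad))
                break
            for (i in seq_along(bad)) {
                span <- start(bad)[i]:end(bad)[i]
                span <- span[!plantCover[span]]
                ch[span] <- .simBase(length(span), config$gcFraction)
            }
            if (round == 100L)
                stop("guard-band cleanup failed for gene ", g,
                     " (background too GC-rich?)")
        }
        seqs[gi] <- paste(ch, collapse = "")
        if (length(off))
            truthRows[[gi]] <- data.frame(
                seq_id = paste0(g, "_prom"), start = W + off + 1L,
                gene_id = g, rel_start = off,
                pattern_id = vapply(words, `[[`, "", "type"),
                stringsAsFactors = FALSE)
    }
    names(seqs) <- paste0(config$geneIds, "_prom")
    tr <- do.call(rbind, truthRows)
    truth <- if (is.null(tr))
        GRanges()
    else {
        g <- GRanges(seqnames = tr$seq_id,
                     ranges = IRanges(start = tr$start, width = 4L),
                     strand = ifelse(tr$pattern_id == "SGSS", "+", "-"))
        mcols(g)$gene_id <- tr$gene_id
        mcols(g)$pattern_id <- tr$pattern_id
        mcols(g)$rel_start <- tr$rel_start
        g
    }
    anchors <- geneAnchors(config$geneIds, paste0(config$geneIds, "_prom"),
                           tss = rep(W, config$nGenes), strand = "+",
                           group = config$groups)
    list(sequences = DNAStringSet(seqs), truth = truth, anchors = anchors)
}

# Planted per-gene log2 fold-change trajectories (the recorded truth).
# Group I trajectories are forced non-increasing so the noiseless series
# always satisfies its own rule.
.simTrajectories <- function(config) {
    out <- vector("list", config$nGenes)
    for (gi in seq_len(config$nGenes)) {
        base <- config$trajectories[[config$groups[gi]]]
        l2 <- base + rnorm(length(base), 0, config$jitterSd)
        if (config$groups[gi] == "I")
            l2 <- cummin(l2)
        out[[gi]] <- l2
    }
    out
}

#' Simulate qPCR and ChIP Ct tables with known truth
#'
#' Encodes planted expression and enrichment trajectories into replicate
#' Ct tables: `Ct = baseline - log2(expression) + N(0, sigma)` for the
#' target, a constant-mean normalizer, and ChIP IP/input pairs whose
#' percent-of-input trajectory is planted per antibody and group.
#'
#' @param config A [simConfig()].
#' @return List with `qpcr` (Ct table), `chip` (Ct table with `antibody`
#'   column), `qpcrTruth` (`gene_id`, `time_h`, `log2_fc_true`, `group`)
#'   and `chipTruth` (`target`, `antibody`, `time_h`,
#'   `percent_input_true`, `relative_to_t0_true`).
#' @export
simCtTables <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 202L)
    reps <- seq_len(config$replicates)
    times <- c(0, config$timesH)
    traj <- .simTrajectories(config)
    qrows <- list(); qtruth <- list()
    for (gi in seq_len(config$nGenes)) {
        g <- config$geneIds[gi]
        l2 <- c(0, traj[[gi]])
        for (ti in seq_along(times)) {
            cond <- if (times[ti] == 0) "untreated" else "OA"
            for (r in reps) {
                noise <- rnorm(2, 0, config$ctSigma)
                qrows[[length(qrows) + 1L]] <- data.frame(
                    sample_id = paste(g, cond, times[ti], r, sep = "_"),
                    target = c(g, "RPLP0"), condition = cond,
                    time_h = times[ti], replicate = r,
                    ct = c(config$baselineCt - l2[ti] + noise[1],
                           config$normalizerCt + noise[2]),
                    stringsAsFactors = FALSE)
            }
        }
        qtruth[[gi]] <- data.frame(gene_id = g, time_h = config$timesH,
                                   log2_fc_true = traj[[gi]],
                                   group = config$groups[gi],
                                   stringsAsFactors = FALSE)
    }
    crows <- list(); ctruth <- list()
    dil <- log2(1 / config$inputFraction)
    for (gi in seq_len(config$nGenes)) {
        g <- config$geneIds[gi]
        for (ab in names(config$chipTrajectories)) {
            pct <- config$chipTrajectories[[ab]][[config$groups[gi]]]
            stopifnot(length(pct) == length(times))
            for (ti in seq_along(times)) {
                cond <- if (times[ti] == 0) "untreated" else "OA"
                ctIpTrue <- config$inputBaseCt - dil - log2(pct[ti] / 100)
                for (r in reps) {
                    crows[[length(crows) + 1L]] <- data.frame(
                        sample_id = paste(g, ab, times[ti], r, sep = "_"),
                        target = g, antibody = c(ab, "input"),
                        condition = cond, time_h = times[ti],
                        replicate = r,
                        ct = c(ctIpTrue + rnorm(1, 0, config$ctSigma),
                               config$inputBaseCt +
                                   rnorm(1, 0, config$ctSigma)),
                        stringsAsFactors = FALSE)
                }
            }
            ctruth[[length(ctruth) + 1L]] <- data.frame(
                target = g, antibody = ab, time_h = times,
                percent_input_true = pct,
                relative_to_t0_true = 100 * pct / pct[1L],
                stringsAsFactors = FALSE)
        }
    }
    list(qpcr = do.call(rbind, qrows), chip = do.call(rbind, crows),
         qpcrTruth = do.call(rbind, qtruth),
         chipTruth = do.call(rbind, ctruth))
}

#' Simulate per-factor peak files with planted associations
#'
#' Places transcription-factor peaks inside the per-gene promoter windows
#' according to each factor's planted association label: a
#' `sensitive_restricted` factor receives peaks only in group I/II
#' windows (at least one), a `ubiquitous` factor in at least half of all
#' windows including at least one group III gene, an `absent` factor in
#' none.
#'
#' @param config A [simConfig()].
#' @return List with `peaks` (named list of `GRanges` on the per-gene
#'   contigs) and `truth` (`data.frame` of factor, planted label).
#' @export
simPeaks <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 303L)
    W <- config$halfWidth
    L <- 2L * W
    contigs <- paste0(config$geneIds, "_prom")
    isIII <- config$groups == "III"
    peaks <- list()
    for (f in names(config$factorLabels)) {
        lab <- config$factorLabels[[f]]
        present <- switch(lab,
            absent = logical(config$nGenes),
            sensitive_restricted = {
                p <- !isIII & runif(config$nGenes) < 0.7
                if (!any(p) && any(!isIII))
                    p[sample(which(!isIII), 1L)] <- TRUE
                p
            },
            ubiquitous = {
                p <- runif(config$nGenes) < 0.8
                if (any(isIII) && !any(p & isIII))
                    p[sample(which(isIII), 1L)] <- TRUE
                while (mean(p) < 0.5)
                    p[sample(which(!p), 1L)] <- TRUE
                p
            },
            stop("unknown factor label '", lab, "' for factor ", f))
        idx <- which(present)
        wdt <- pmax(50L, round(rnorm(length(idx), config$peakWidth,
                                     config$peakWidth / 4)))
        ctr <- sample(seq_len(L), length(idx), replace = TRUE)
        st <- pmax(1L, ctr - wdt %/% 2L)
        en <- pmin(L, st + wdt - 1L)
        peaks[[f]] <- GRanges(seqnames = contigs[idx],
                              ranges = IRanges(st, en))
    }
    list(peaks = peaks,
         truth = data.frame(factor = names(config$factorLabels),
                            label = unname(config$factorLabels),
                            stringsAsFactors = FALSE))
}

#' Run the full synthetic study
#'
#' Convenience wrapper calling [simPromoters()], [simCtTables()] and
#' [simPeaks()] on one configuration.
#'
#' @param config A [simConfig()].
#' @return List with elements `config`, `promoters`, `ct`, `peaks`.
#' @export
simStudy <- function(config) {
    list(config = config, promoters = simPromoters(config),
         ct = simCtTables(config), peaks = simPeaks(config))
}
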