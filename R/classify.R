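#' Thresholds for transcriptional sensitivity grouping
#'
#' Tunable bands operationalizing the three observed response classes to a
#' GC-binding transcriptional inhibitor. Defaults are documented
#' interpretations of the qualitative wording, not measured constants:
#' a two-fold drop defines "decreased two-fold" (`fcHalf = 0.5`); the
#' "~50% by 12 h" band is `bandII = 0.55`; "changed insignificantly" is
#' `|log2 FC| <= log2(bandIII)` with `bandIII = 1.5`; and "continued to
#' decrease" tolerates a multiplicative wobble `tau = 1.1` between
#' consecutive points.
#'
#' @param fcHalf Fold-change threshold for the early two-fold drop.
#' @param earlyTimes Times (h) in which the early drop may occur.
#' @param finalTime The end-point time (h) that must be present.
#' @param bandII Fold-change ceiling at `finalTime` for group II.
#' @param bandIII Fold-change band (ratio) for "insignificant" change.
#' @param tau Multiplicative tolerance for "non-increasing".
#' @return Named list of thresholds.
#' @export
responseThresholds <- function(fcHalf = 0.5, earlyTimes = c(1, 3, 6),
                               finalTime = 12, bandII = 0.55,
                               bandIII = 1.5, tau = 1.1) {
    stopifnot(fcHalf > 0, bandII > 0, bandIII >= 1, tau >= 1,
              length(finalTime) == 1L)
    list(fcHalf = fcHalf, earlyTimes = earlyTimes, finalTime = finalTime,
         bandII = bandII, bandIII = bandIII, tau = tau)
}

#' Classify one gene's fold-change time course
#'
#' Assigns a fold-change trajectory to one of three sensitivity groups:
#' \itemize{
#' \item \strong{I} (highly sensitive): fold change at or below `fcHalf`
#'   at some early time (1-6 h) and non-increasing (within tolerance
#'   `tau`) from that point through the 12 h end point;
#' \item \strong{II} (averagely sensitive): not I, and the 12 h fold
#'   change is at or below `bandII`;
#' \item \strong{III} (weakly sensitive): every |log2 fold change| within
#'   `log2(bandIII)`.
#' }
#' A series matching none of the rules is resolved to the nearer of II and
#' III by distance on the log2 scale, with the ambiguity recorded in the
#' trace.
#'
#' @param fc Positive fold changes (untreated = 1).
#' @param timesH Times in hours, aligned with `fc`; must include the end
#'   point (12 h by default) and at least one early time.
#' @param thresholds See [responseThresholds()].
#' @return List with `group` (`"I"`,`"II"`,`"III"`), `trace` (which rule
#'   fired and where) and the input series.
#' @examples
#' classifyResponse(c(0.5, 0.4, 0.3, 0.2), c(1, 3, 6, 12))$group  # "I"
#' classifyResponse(c(0.9, 0.8, 0.7, 0.5), c(1, 3, 6, 12))$group  # "II"
#' classifyResponse(c(1, 1, 1, 1), c(1, 3, 6, 12))$group          # "III"
#' @export
classifyResponse <- function(fc, timesH, thresholds = responseThresholds()) {
    th <- thresholds
    if (length(fc) != length(timesH))
        stop("'fc' and 'timesH' lengths differ")
    if (any(!is.finite(fc) | fc <= 0))
        stop("fold changes must be positive and finite")
    if (!th$finalTime %in% timesH)
        stop("missing ", th$finalTime, " h point")
    if (!any(th$earlyTimes %in% timesH))
        stop("no early time point (", paste(th$earlyTimes, collapse = "/"),
             " h) in series")
    o <- order(timesH)
    fc <- fc[o]; timesH <- timesH[o]
    fcFinal <- fc[timesH == th$finalTime][1L]

    # group I: early two-fold drop sustained to the end point
    for (tStar in intersect(th$earlyTimes, timesH)) {
        iStar <- which(timesH == tStar)[1L]
        if (fc[iStar] > th$fcHalf)
            next
        tail <- fc[iStar:length(fc)]
        if (all(diff(tail) <= tail[-length(tail)] * (th$tau - 1)))
            return(list(group = "I",
                        trace = sprintf(
                            "I: fc=%.3g <= %.2g at %g h, non-increasing (tau=%.2g) through %g h",
                            fc[iStar], th$fcHalf, tStar, th$tau,
                            th$finalTime),
                        fc = fc, times_h = timesH))
    }
    if (fcFinal <= th$bandII)
        return(list(group = "II",
                    trace = sprintf("II: fc(%g h)=%.3g <= %.2g",
                                    th$finalTime, fcFinal, th$bandII),
                    fc = fc, times_h = timesH))
    if (all(abs(log2(fc)) <= log2(th$bandIII)))
        return(list(group = "III",
                    trace = sprintf("III: all |log2 fc| <= log2(%.2g)",
                                    th$bandIII),
                    fc = fc, times_h = timesH))
    dII <- max(0, log2(fcFinal) - log2(th$bandII))
    dIII <- max(0, max(abs(log2(fc))) - log2(th$bandIII))
    grp <- if (dII <= dIII) "II" else "III"
    list(group = grp,
         trace = sprintf(
             "ambiguous: resolved to %s by log2 distance (d_II=%.3g, d_III=%.3g)",
             grp, dII, dIII),
         fc = fc, times_h = timesH)
}

#' Classify a cohort of expression time courses
#'
#' @param results `data.frame` with columns `gene_id`, `time_h`,
#'   `fold_change` (e.g. stacked [deltaDeltaCt()] outputs); the reference
#'   time point (fold change 1) may be present and is ignored for rule
#'   evaluation only when it is not among the analyzed times.
#' @param thresholds See [responseThresholds()].
#' @return `data.frame` with one row per gene: `gene_id`, `group`,
#'   `trace`; group counts are attached as `attr(, "counts")`.
#' @examples
#' df <- data.frame(gene_id = "g1", time_h = c(1, 3, 6, 12),
#'                  fold_change = c(0.5, 0.4, 0.3, 0.2))
#' classifyCohort(df)
#' @export
classifyCohort <- function(results, thresholds = responseThresholds()) {
    stopifnot(all(c("gene_id", "time_h", "fold_change") %in%
                  names(results)))
    genes <- unique(results$gene_id)
    rows <- lapply(genes, function(g) {
        d <- results[results$gene_id == g, ]
        keep <- d$time_h %in% c(thresholds$earlyTimes, thresholds$finalTime)
        call <- classifyResponse(d$fold_change[keep], d$time_h[keep],
                                 thresholds)
        data.frame(gene_id = g, group = call$group, trace = call$trace,
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(gene_id = character(0), group = character(0),
                           trace = character(0))
    attr(out, "counts") <- table(factor(out$group,
                                        levels = c("I", "II", "III")))
    out
}
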