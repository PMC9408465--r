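#' @importFrom stats aggregate var setNames
NULL

#' Relative expression by the delta-delta Ct method
#'
#' Computes per-condition relative expression of a target gene against a
#' reference-gene normalizer (default `RPLP0`):
#' \deqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{normalizer}}
#' \deqn{\Delta\Delta Ct = \Delta Ct_{condition} - \Delta Ct_{reference}}
#' \deqn{FC = E^{-\Delta\Delta Ct}}
#' with amplification efficiency `E` fixed at 2 unless a standard curve
#' says otherwise. Replicates are averaged on the Ct scale; the log2-scale
#' SD is propagated in quadrature from the replicate variances of the four
#' means involved.
#'
#' @param ct Ct table `data.frame` with columns `target`, `condition`,
#'   `time_h`, `replicate`, `ct` (see [readCtTable()]).
#' @param target Target gene/amplicon name.
#' @param normalizer Normalizer gene name; default `"RPLP0"`. Missing
#'   normalizer rows for any condition are an error.
#' @param referenceCondition,referenceTime Condition label and time (h)
#'   of the reference (untreated, 0 h by default); its fold change is 1 by
#'   construction.
#' @param efficiency Amplification efficiency; default 2 (one Ct cycle =
#'   one two-fold change).
#' @return `data.frame` with one row per (condition, time): `delta_ct`,
#'   `ddct`, `fold_change`, `sd_log2`, replicate counts and a
#'   `warn_replicates` flag (fewer than 3 replicates; `sd_log2` is `NA`
#'   for single replicates).
#' @examples
#' ct <- data.frame(
#'   target = rep(c("MYC", "RPLP0"), each = 2),
#'   condition = rep(c("untreated", "OA"), 2),
#'   time_h = rep(c(0, 3), 2), replicate = 1,
#'   ct = c(20, 23, 15, 15))
#' deltaDeltaCt(ct, "MYC")  # fold change 0.125 at 3 h
#' @export
deltaDeltaCt <- function(ct, target, normalizer = "RPLP0",
                         referenceCondition = "untreated",
                         referenceTime = 0, efficiency = 2) {
    need <- c("target", "condition", "time_h", "replicate", "ct")
    miss <- setdiff(need, names(ct))
    if (length(miss))
        stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
    if (!any(ct$target == normalizer))
        stop("normalizer '", normalizer, "' not found in Ct table")
    if (!any(ct$target == target))
        stop("target '", target, "' not found in Ct table")
    sub <- ct[ct$target %in% c(target, normalizer), , drop = FALSE]
    agg <- aggregate(ct ~ target + condition + time_h, data = sub,
                     FUN = function(x) c(m = mean(x), v = var(x),
                                         n = length(x)))
    agg <- cbind(agg[c("target", "condition", "time_h")],
                 as.data.frame(agg$ct))
    key <- function(d) paste(d$condition, d$time_h)
    tg <- agg[agg$target == target, ]
    nm <- agg[agg$target == normalizer, ]
    if (!all(key(tg) %in% key(nm)))
        stop("normalizer '", normalizer,
             "' missing for condition(s): ",
             paste(setdiff(key(tg), key(nm)), collapse = ", "))
    nm <- nm[match(key(tg), key(nm)), ]
    refIdx <- which(tg$condition == referenceCondition &
                    tg$time_h == referenceTime)
    if (length(refIdx) != 1L)
        stop("reference condition '", referenceCondition, "' at ",
             referenceTime, " h not found (or not unique) for target '",
             target, "'")
    dct <- tg$m - nm$m
    ddct <- dct - dct[refIdx]
    # variance of each of the four means; reference contributes to every
    # non-reference condition
    vmean <- function(v, n) ifelse(n > 1, v / n, NA_real_)
    vCond <- vmean(tg$v, tg$n) + vmean(nm$v, nm$n)
    vRef <- vCond[refIdx]
    sdl2 <- sqrt(vCond + ifelse(seq_along(vCond) == refIdx, 0, vRef)) *
        log2(efficiency)
    warnRep <- tg$n < 3 | nm$n < 3
    if (any(warnRep))
        warning("fewer than 3 replicates for some condition(s); ",
                "SD is unreliable (triplicates expected)")
    data.frame(target = target, normalizer = normalizer,
               condition = tg$condition, time_h = tg$time_h,
               n_target = tg$n, n_normalizer = nm$n,
               delta_ct = dct, ddct = ddct,
               fold_change = efficiency^(-ddct), sd_log2 = sdl2,
               warn_replicates = warnRep, stringsAsFactors = FALSE)
}

#' ChIP enrichment as percent of input
#'
#' Converts IP and input Ct values into the percent-of-input enrichment,
#' adjusting the input Ct for the fraction of chromatin it represents
#' (dilution factor `1 / inputFraction`):
#' \deqn{Ct_{input}^{adj} = Ct_{input} - \log_2(1/f)}
#' \deqn{\%input = 100 \times 2^{\,Ct_{input}^{adj} - Ct_{IP}}}
#' The input fraction has no default: it must be stated, so a wrong
#' dilution can never be silently assumed.
#'
#' @param ctIp Numeric vector of IP Ct values.
#' @param ctInput Numeric vector of input Ct values (recycled).
#' @param inputFraction Fraction of chromatin used as input, in (0, 1].
#' @return Numeric vector of percent-of-input values.
#' @examples
#' percentInput(25, 25, 1)          # 100
#' percentInput(27, 25, 1)          # 25
#' percentInput(22, 25, 0.01)       # ~8.0
#' @export
percentInput <- function(ctIp, ctInput, inputFraction) {
    if (!is.numeric(inputFraction) || length(inputFraction) != 1L ||
        is.na(inputFraction) || inputFraction <= 0 || inputFraction > 1)
        stop("'inputFraction' must be a single number in (0, 1]")
    adj <- ctInput - log2(1 / inputFraction)
    100 * 2^(adj - ctIp)
}

#' Percent-of-input time courses from a ChIP Ct table
#'
#' Collapses replicates by Ct-scale mean and computes percent of input per
#' (target, antibody, time) against the matching input sample.
#'
#' @param ct ChIP Ct table with columns `target`, `antibody`, `condition`,
#'   `time_h`, `replicate`, `ct`; rows with `antibody == inputLabel` are
#'   the dilution-adjusted input controls.
#' @param inputFraction See [percentInput()].
#' @param inputLabel Antibody label of input rows; default `"input"`.
#' @return `data.frame` with `target`, `antibody`, `time_h`,
#'   `percent_input` and replicate count `n`.
#' @seealso [normalizeToT0()]
#' @export
chipPercentInput <- function(ct, inputFraction, inputLabel = "input") {
    need <- c("target", "antibody", "time_h", "replicate", "ct")
    miss <- setdiff(need, names(ct))
    if (length(miss))
        stop("ChIP Ct table is missing column(s): ",
             paste(miss, collapse = ", "))
    if (!any(ct$antibody == inputLabel))
        stop("no input rows (antibody == '", inputLabel, "')")
    agg <- aggregate(ct ~ target + antibody + time_h, data = ct,
                     FUN = function(x) c(m = mean(x), n = length(x)))
    agg <- cbind(agg[c("target", "antibody", "time_h")],
                 as.data.frame(agg$ct))
    inp <- agg[agg$antibody == inputLabel, ]
    ip <- agg[agg$antibody != inputLabel, ]
    ki <- paste(inp$target, inp$time_h)
    kp <- paste(ip$target, ip$time_h)
    if (!all(kp %in% ki))
        stop("missing input sample for: ",
             paste(setdiff(kp, ki), collapse = ", "))
    inp <- inp[match(kp, ki), ]
    data.frame(target = ip$target, antibody = ip$antibody,
               time_h = ip$time_h,
               percent_input = percentInput(ip$m, inp$m, inputFraction),
               n = ip$n, stringsAsFactors = FALSE)
}

#' Normalize an enrichment series to its 0 h point
#'
#' Rescales a percent-of-input time course so that the untreated 0 h
#' value reads 100 (the convention used to plot enrichment dynamics).
#'
#' @param df `data.frame` from [chipPercentInput()] (or any table with
#'   `time_h` and `percent_input`); series are formed per (target,
#'   antibody) when those columns are present.
#' @param t0 Reference time in hours; default 0. A missing or zero 0 h
#'   value is an error.
#' @return Input `data.frame` with an added `relative_to_t0` column
#'   (exactly 100 at `t0`).
#' @examples
#' normalizeToT0(data.frame(time_h = c(0, 3), percent_input = c(4, 2)))
#' @export
normalizeToT0 <- function(df, t0 = 0) {
    stopifnot(all(c("time_h", "percent_input") %in% names(df)))
    keyCols <- intersect(c("target", "antibody"), names(df))
    key <- if (length(keyCols))
        interaction(df[keyCols], drop = TRUE) else factor(rep(1, nrow(df)))
    out <- df
    out$relative_to_t0 <- NA_real_
    for (k in levels(key)) {
        i <- which(key == k)
        i0 <- i[df$time_h[i] == t0]
        if (!length(i0))
            stop("no ", t0, " h point in series ", k)
        v0 <- mean(df$percent_input[i0])
        if (!is.finite(v0) || v0 <= 0)
            stop("non-positive ", t0, " h value in series ", k)
        out$relative_to_t0[i] <- 100 * df$percent_input[i] / v0
    }
    out
}
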