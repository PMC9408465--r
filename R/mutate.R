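#' Design a tetrad-abrogated mutant sequence
#'
#' Implements the tetrad-abrogation procedure used to turn a wild-type
#' promoter into its binding-dead variant: every unprotected drug-binding
#' tetrad is destroyed by substituting the obligate guanine of the site
#' (G\eqn{\rightarrow}A on the strand carrying it, i.e. G\eqn{\rightarrow}A
#' or C\eqn{\rightarrow}T on the forward strand), leaving protected
#' intervals — such as an MluI cloning site — untouched.
#'
#' The algorithm is a deterministic leftmost-first greedy with rescan to
#' fixpoint: scan, pick the leftmost unprotected site, substitute its
#' obligate position (for an `SGSS` match, pattern position 2, G to A; for
#' an `SSCS` match, pattern position 3, C to T), rescan. Since each edit
#' replaces a G/C with an A/T it can never create a new all-G/C tetrad, so
#' the loop strictly shrinks the site set. Sites lying wholly inside a
#' protected interval are reported as residual; a site whose every
#' obligate position is protected while the site itself is not fully
#' protected is an unresolvable conflict and is reported, never silently
#' skipped.
#'
#' @param seq Input sequence (character, [Biostrings::DNAString], or
#'   length-1 [Biostrings::DNAStringSet]).
#' @param patterns List of [MotifPattern][MotifPattern-class]s or pattern
#'   strings; default [oaPatterns()] (`SGSS` + `SSCS`). Every pattern must
#'   have at least one obligate G or C position.
#' @param protected [IRanges::IRanges] of 1-based intervals to leave
#'   untouched (may be empty).
#' @param seqId Sequence name for reported sites.
#' @return List with `mutant` ([Biostrings::DNAString]) and `plan`
#'   ([MutagenesisPlan][MutagenesisPlan-class]).
#' @examples
#' res <- designMutant("TGGGGT")
#' as.character(res$mutant)          # "TGAGGT"
#' substitutions(res$plan)
#' @seealso [verifyPlan()]
#' @export
designMutant <- function(seq, patterns = oaPatterns(),
                         protected = IRanges(), seqId = "seq") {
    patterns <- lapply(patterns, function(p)
        if (is.character(p)) parsePattern(p) else p)
    if (is.null(names(patterns)))
        names(patterns) <- vapply(patterns, patternId, character(1))
    for (p in patterns)
        if (!length(obligatePositions(p)))
            stop(sprintf("pattern '%s' has no obligate G or C position",
                         patternId(p)))
    ch <- .subjectChars(seq)
    n <- length(ch)
    if (length(protected) &&
        (min(start(protected)) < 1L || max(end(protected)) > n))
        stop("protected intervals must lie within sequence bounds")
    protCover <- rep(FALSE, n)
    for (i in seq_along(protected))
        protCover[start(protected)[i]:end(protected)[i]] <- TRUE

    subs <- list()
    iter <- 0L
    cap <- sum(ch %in% c("G", "C")) + 1L
    repeat {
        act <- .firstActionable(ch, patterns, protCover)
        if (is.null(act))
            break
        iter <- iter + 1L
        if (iter > cap)
            stop("mutant design did not converge (iteration cap exceeded)")
        pos <- act$editPos
        from <- ch[pos]
        to <- if (from == "G") "A" else "T"
        ch[pos] <- to
        subs[[iter]] <- data.frame(
            position = pos, from = from, to = to,
            strand = if (from == "G") "+" else "-",
            pattern_id = act$pattern_id, stringsAsFactors = FALSE)
    }

    final <- .classifySites(ch, patterns, protCover, seqId)
    plan <- new("MutagenesisPlan",
                substitutions = if (length(subs)) do.call(rbind, subs)
                    else data.frame(position = integer(0),
                                    from = character(0), to = character(0),
                                    strand = character(0),
                                    pattern_id = character(0)),
                protected = protected,
                residualSites = final$residual,
                conflicts = final$conflicts,
                iterations = iter)
    list(mutant = DNAString(paste(ch, collapse = "")), plan = plan)
}

# Leftmost unprotected site with an editable obligate position, or NULL.
# Leftmost-first tie-break: ascending start, then pattern list order.
.firstActionable <- function(ch, patterns, protCover) {
    best <- NULL
    for (k in seq_along(patterns)) {
        p <- patterns[[k]]
        w <- length(p@baseSets)
        for (o in .matchOffsets(ch, p)) {
            span <- (o + 1L):(o + w)
            if (all(protCover[span]))
                next                       # fully protected: residual
            obl <- vapply(obligatePositions(p), `[[`, 0L, "position") + o
            free <- obl[!protCover[obl]]
            if (!length(free))
                next                       # conflict: reported at the end
            cand <- list(start = o + 1L, order = k, editPos = free[1L],
                         pattern_id = patternId(p))
            if (is.null(best) || cand$start < best$start ||
                (cand$start == best$start && cand$order < best$order))
                best <- cand
        }
    }
    best
}

# Scan and split sites into residual (fully protected, merged into
# discrete regions) and conflicts (unprotected but with every obligate
# position protected).
.classifySites <- function(ch, patterns, protCover, seqId) {
    res <- list(); conf <- list()
    for (p in patterns) {
        w <- length(p@baseSets)
        for (o in .matchOffsets(ch, p)) {
            span <- (o + 1L):(o + w)
            gr <- .sitesGRanges(ch, o, w, "+", patternId(p), seqId)
            if (all(protCover[span]))
                res[[length(res) + 1L]] <- gr
            else
                conf[[length(conf) + 1L]] <- gr
        }
    }
    empty <- .sitesGRanges(character(0), integer(0), 0L, "+", "", "seq")
    list(residual = if (length(res))
             mergeSites(do.call(c, res), byStrand = FALSE) else empty,
         conflicts = if (length(conf))
             sort(do.call(c, conf), ignore.strand = TRUE) else empty)
}

#' Verify a mutagenesis plan against its sequences
#'
#' Independent audit of a [designMutant()] result: the sequence diff must
#' equal the substitution list exactly (no undeclared or missing edits),
#' every substitution must be a forward-strand G to A or C to T outside
#' the protected intervals, and rescanning the mutant must find sites only
#' inside protected intervals (the declared residual set) or among the
#' declared unresolvable conflicts — no new sites.
#'
#' @param original,mutant Sequences of equal length.
#' @param plan A [MutagenesisPlan][MutagenesisPlan-class].
#' @param patterns Patterns the design used; default [oaPatterns()].
#' @return List with `ok` (logical) and `failures` (character vector of
#'   named violations, empty when `ok`).
#' @examples
#' res <- designMutant("TGGGGT")
#' verifyPlan("TGGGGT", res$mutant, res$plan)$ok
#' @export
verifyPlan <- function(original, mutant, plan, patterns = oaPatterns()) {
    stopifnot(is(plan, "MutagenesisPlan"))
    patterns <- lapply(patterns, function(p)
        if (is.character(p)) parsePattern(p) else p)
    co <- .subjectChars(original)
    cm <- .subjectChars(mutant)
    fails <- character(0)
    if (length(co) != length(cm))
        return(list(ok = FALSE, failures = "length mismatch"))
    s <- plan@substitutions
    diff <- which(co != cm)
    extra <- setdiff(diff, s$position)
    if (length(extra))
        fails <- c(fails, sprintf("undeclared edit at position %s",
                                  paste(extra, collapse = ",")))
    missing <- setdiff(s$position, diff)
    if (length(missing))
        fails <- c(fails, sprintf("declared edit not applied at position %s",
                                  paste(missing, collapse = ",")))
    if (nrow(s)) {
        badFrom <- s$position[co[s$position] != s$from]
        if (length(badFrom))
            fails <- c(fails, sprintf("original base mismatch at position %s",
                                      paste(badFrom, collapse = ",")))
        badTo <- s$position[cm[s$position] != s$to]
        if (length(badTo))
            fails <- c(fails, sprintf("mutant base mismatch at position %s",
                                      paste(badTo, collapse = ",")))
        badEdit <- !((s$from == "G" & s$to == "A") |
                     (s$from == "C" & s$to == "T"))
        if (any(badEdit))
            fails <- c(fails, "substitution is not G>A or C>T")
        if (length(plan@protected) &&
            any(IRanges::overlapsAny(IRanges(s$position, s$position),
                                     plan@protected)))
            fails <- c(fails, "protected violation")
    }
    protCover <- rep(FALSE, length(cm))
    for (i in seq_along(plan@protected))
        protCover[start(plan@protected)[i]:end(plan@protected)[i]] <- TRUE
    found <- .classifySites(cm, patterns, protCover, "seq")
    declaredConf <- paste(start(plan@conflicts), end(plan@conflicts),
                          mcols(plan@conflicts)$pattern_id)
    openConf <- paste(start(found$conflicts), end(found$conflicts),
                      mcols(found$conflicts)$pattern_id)
    undecl <- setdiff(openConf, declaredConf)
    if (length(undecl))
        fails <- c(fails, sprintf("unprotected site remains at %s",
                                  paste(undecl, collapse = "; ")))
    declaredRes <- paste(start(plan@residualSites), end(plan@residualSites),
                         mcols(plan@residualSites)$pattern_id)
    openRes <- setdiff(paste(start(found$residual), end(found$residual),
                             mcols(found$residual)$pattern_id), declaredRes)
    if (length(openRes))
        fails <- c(fails, sprintf("undeclared residual site at %s",
                                  paste(openRes, collapse = "; ")))
    list(ok = length(fails) == 0L, failures = fails)
}
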