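#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
NULL

#' MotifPattern: a degenerate nucleotide pattern
#'
#' A `MotifPattern` describes a short degenerate DNA motif as an ordered
#' vector of IUPAC nucleotide codes, e.g. the GC-tetrad consensus `SGSS`
#' (S = G or C) bound by aureolic-acid antibiotics in the DNA minor groove.
#' Positions whose code expands to the single base G (or C, representing a
#' guanine on the reverse strand) are the *obligate* positions: the guanine
#' amino group there is required for drug binding, and it is the base
#' targeted by tetrad-abrogating mutagenesis.
#'
#' @slot id Single character, short pattern name (e.g. `"SGSS"`).
#' @slot symbols Character vector of single IUPAC codes, one per position.
#' @slot baseSets List of character vectors; element `i` is the set of
#'   concrete bases (`A`,`C`,`G`,`T`) matched at position `i`.
#'
#' @seealso [parsePattern()], [oaPatterns()], [scanPattern()]
#' @exportClass MotifPattern
setClass("MotifPattern",
    representation(id = "character", symbols = "character",
                   baseSets = "list"))

setValidity("MotifPattern", function(object) {
    msg <- NULL
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@symbols) < 1L)
        msg <- c(msg, "pattern must have length >= 1")
    if (length(object@baseSets) != length(object@symbols))
        msg <- c(msg, "'baseSets' and 'symbols' lengths differ")
    bad <- !object@symbols %in% names(IUPAC_SETS)
    if (any(bad))
        msg <- c(msg, sprintf("invalid IUPAC code '%s' at position %d",
                              object@symbols[which(bad)[1L]], which(bad)[1L]))
    for (i in seq_along(object@baseSets)) {
        expect <- IUPAC_SETS[[object@symbols[i]]]
        if (!setequal(object@baseSets[[i]], expect)) {
            msg <- c(msg, sprintf("baseSets[[%d]] inconsistent with symbol '%s'",
                                  i, object@symbols[i]))
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' MutagenesisPlan: a tetrad-abrogation design
#'
#' Produced by [designMutant()]. Records the single-base substitutions
#' (G\eqn{\rightarrow}A on the strand carrying the obligate guanine, i.e.
#' G\eqn{\rightarrow}A or C\eqn{\rightarrow}T on the forward strand) that
#' remove every unprotected tetrad site from a sequence, the intervals that
#' were left untouched (e.g. an MluI cloning site), the residual sites that
#' survive inside protected intervals, and any unresolvable conflicts.
#'
#' @slot substitutions `data.frame` with columns `position` (1-based),
#'   `from`, `to`, `strand` (`+` for a forward-strand G edit, `-` when the
#'   obligate guanine lies on the reverse strand and the forward-strand
#'   edit is C to T), and `pattern_id`.
#' @slot protected [IRanges::IRanges] of intervals that must not be edited.
#' @slot residualSites [GenomicRanges::GRanges] of sites remaining wholly
#'   inside protected intervals, merged into discrete regions.
#' @slot conflicts [GenomicRanges::GRanges] of sites that could not be
#'   abrogated because every obligate position lies inside a protected
#'   interval while the site itself is not fully protected.
#' @slot iterations Integer, number of greedy substitution rounds used.
#'
#' @seealso [designMutant()], [verifyPlan()]
#' @exportClass MutagenesisPlan
setClass("MutagenesisPlan",
    representation(substitutions = "data.frame", protected = "IRanges",
                   residualSites = "GRanges", conflicts = "GRanges",
                   iterations = "integer"))

setValidity("MutagenesisPlan", function(object) {
    msg <- NULL
    s <- object@substitutions
    need <- c("position", "from", "to", "strand", "pattern_id")
    if (!all(need %in% names(s)))
        msg <- c(msg, "substitutions must have columns position/from/to/strand/pattern_id")
    else if (nrow(s)) {
        okEdit <- (s$from == "G" & s$to == "A") | (s$from == "C" & s$to == "T")
        if (!all(okEdit))
            msg <- c(msg, "every substitution must be G->A or C->T on the forward strand")
        if (length(object@protected) &&
            any(IRanges::overlapsAny(IRanges(s$position, s$position),
                                     object@protected)))
            msg <- c(msg, "a substitution lies inside a protected interval")
    }
    if (length(object@iterations) != 1L || object@iterations < 0L)
        msg <- c(msg, "'iterations' must be a single non-negative integer")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MotifPattern-class Compact display.
#' @param object A `MotifPattern`.
#' @export
setMethod("show", "MotifPattern", function(object) {
    cat(sprintf("MotifPattern '%s': %s (width %d)\n", object@id,
                paste(object@symbols, collapse = ""), length(object@symbols)))
    ob <- obligatePositions(object)
    if (length(ob))
        cat(sprintf("  obligate %s at position(s) %s (1-based)\n",
                    paste(unique(vapply(ob, `[[`, "", "base")), collapse = "/"),
                    paste(vapply(ob, `[[`, 0L, "position"), collapse = ", ")))
    invisible(NULL)
})

#' @describeIn MutagenesisPlan-class Compact display.
#' @param object A `MutagenesisPlan`.
#' @export
setMethod("show", "MutagenesisPlan", function(object) {
    cat(sprintf(paste0("MutagenesisPlan: %d substitution(s), %d protected ",
                       "interval(s),\n  %d residual site(s), %d conflict(s), ",
                       "%d iteration(s)\n"),
                nrow(object@substitutions), length(object@protected),
                length(object@residualSites), length(object@conflicts),
                object@iterations))
    if (nrow(object@substitutions)) {
        s <- utils::head(object@substitutions, 5L)
        cat(paste(sprintf("  pos %d: %s>%s (%s, %s)", s$position, s$from,
                          s$to, s$strand, s$pattern_id), collapse = "\n"), "\n")
        if (nrow(object@substitutions) > 5L)
            cat(sprintf("  ... and %d more\n", nrow(object@substitutions) - 5L))
    }
    invisible(NULL)
})

#' @rdname MutagenesisPlan-class
#' @param plan A `MutagenesisPlan`.
#' @export
substitutions <- function(plan) {
    stopifnot(is(plan, "MutagenesisPlan"))
    plan@substitutions
}

#' @rdname MutagenesisPlan-class
#' @export
residualSites <- function(plan) {
    stopifnot(is(plan, "MutagenesisPlan"))
    plan@residualSites
}

#' @rdname MutagenesisPlan-class
#' @export
planConflicts <- function(plan) {
    stopifnot(is(plan, "MutagenesisPlan"))
    plan@conflicts
}
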