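# IUPAC nucleotide code expansion. Subject sequences may contain N, but a
# subject N never satisfies any pattern position (conservative site calling):
# the base sets below contain concrete A/C/G/T only, so "N" %in% set is FALSE.
IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Parse a degenerate IUPAC pattern
#'
#' Builds a [MotifPattern][MotifPattern-class] from a degenerate pattern
#' string such as `"SGSS"` (S = G or C), the consensus GC tetrad bound by
#' olivomycin A and related aureolic-acid antibiotics.
#'
#' @param text Pattern string; lower case is accepted and normalized.
#' @param id Pattern name recorded in scan results; defaults to the
#'   normalized pattern string.
#' @return A `MotifPattern`.
#' @examples
#' parsePattern("SGSS")
#' baseSets(parsePattern("sgss"))
#' @export
parsePattern <- function(text, id = toupper(text)) {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(text))
        stop("'text' must be a single non-empty pattern string")
    sym <- strsplit(toupper(text), "", fixed = TRUE)[[1L]]
    bad <- which(!sym %in% names(IUPAC_SETS))
    if (length(bad))
        stop(sprintf("invalid IUPAC code '%s' at position %d of pattern '%s'",
                     sym[bad[1L]], bad[1L], toupper(text)))
    new("MotifPattern", id = id, symbols = sym,
        baseSets = unname(IUPAC_SETS[sym]))
}

#' Default aureolic-acid binding-site patterns
#'
#' The two degenerate tetrads used as putative olivomycin A binding sites:
#' `SGSS` and its reverse complement `SSCS` (S = G or C). Scanning a
#' forward strand for both is equivalent to scanning both strands for
#' `SGSS`.
#'
#' @return Named list of two [MotifPattern][MotifPattern-class] objects.
#' @examples
#' oaPatterns()
#' @export
oaPatterns <- function() {
    list(SGSS = parsePattern("SGSS"), SSCS = parsePattern("SSCS"))
}

#' @rdname MotifPattern-class
#' @param pattern A `MotifPattern`.
#' @export
patternId <- function(pattern) {
    stopifnot(is(pattern, "MotifPattern"))
    pattern@id
}

#' @rdname MotifPattern-class
#' @export
patternString <- function(pattern) {
    stopifnot(is(pattern, "MotifPattern"))
    paste(pattern@symbols, collapse = "")
}

#' @rdname MotifPattern-class
#' @export
baseSets <- function(pattern) {
    stopifnot(is(pattern, "MotifPattern"))
    pattern@baseSets
}

#' @rdname MotifPattern-class
#' @details `obligatePositions()` returns, for each pattern position whose
#'   base set is exactly `{G}` or exactly `{C}`, the 1-based position and
#'   the base. A fixed G marks the obligate guanine on the pattern's
#'   strand; a fixed C marks an obligate guanine on the reverse strand.
#' @export
obligatePositions <- function(pattern) {
    stopifnot(is(pattern, "MotifPattern"))
    out <- list()
    for (i in seq_along(pattern@baseSets)) {
        s <- pattern@baseSets[[i]]
        if (length(s) == 1L && s %in% c("G", "C"))
            out[[length(out) + 1L]] <- list(position = i, base = s)
    }
    out
}

#' @describeIn MotifPattern-class Reverse complement of a degenerate
#'   pattern (e.g. `SGSS` to `SSCS`).
#' @param x A `MotifPattern`.
#' @param ... Ignored.
#' @importFrom Biostrings reverseComplement
#' @export
setMethod("reverseComplement", "MotifPattern", function(x, ...) {
    sym <- rev(unname(IUPAC_COMPLEMENT[x@symbols]))
    parsePattern(paste(sym, collapse = ""), id = paste0("rc(", x@id, ")"))
})
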