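#' @importFrom GenomicRanges GRanges granges reduce findOverlaps
#' @importFrom IRanges IRanges ranges
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet
#' @importFrom BiocGenerics start end width strand strand<- sort
NULL

# Normalize a subject sequence to an uppercase character vector of bases.
# Accepts character, DNAString or a length-1 DNAStringSet. Subjects may
# contain A/C/G/T/N only; N never matches (see IUPAC_SETS).
.subjectChars <- function(seq) {
    if (is(seq, "DNAStringSet")) {
        stopifnot(length(seq) == 1L)
        seq <- seq[[1L]]
    }
    if (is(seq, "DNAString"))
        seq <- as.character(seq)
    if (!is.character(seq) || length(seq) != 1L || is.na(seq))
        stop("'seq' must be a single DNA sequence (character or DNAString)")
    ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop(sprintf("invalid base '%s' at position %d (only A/C/G/T/N allowed)",
                     ch[bad[1L]], bad[1L]))
    ch
}

# 0-based match offsets of a MotifPattern in a character vector of bases.
# Position-wise vectorized set membership; overlapping matches all reported.
.matchOffsets <- function(ch, pattern) {
    m <- length(pattern@baseSets)
    n <- length(ch)
    if (n < m)
        return(integer(0))
    ok <- rep(TRUE, n - m + 1L)
    for (j in seq_len(m)) {
        ok <- ok & ch[j:(n - m + j)] %in% pattern@baseSets[[j]]
        if (!any(ok))
            return(integer(0))
    }
    which(ok) - 1L
}

.sitesGRanges <- function(ch, offsets, width, strand, patternId, seqId) {
    if (!length(offsets))
        return(GRanges(seqnames = character(0), ranges = IRanges(),
                       strand = character(0),
                       pattern_id = character(0), matched_seq = character(0)))
    gr <- GRanges(seqnames = seqId,
                  ranges = IRanges(start = offsets + 1L,
                                   width = rep(width, length(offsets))),
                  strand = strand)
    mcols(gr)$pattern_id <- patternId
    mcols(gr)$matched_seq <- vapply(offsets, function(o)
        paste(ch[(o + 1L):(o + width)], collapse = ""), character(1))
    gr
}

#' Scan a sequence for a degenerate tetrad pattern
#'
#' Reports every forward-strand occurrence of a degenerate IUPAC pattern in
#' a DNA sequence, overlapping matches included, in ascending start order.
#' Matching is case-insensitive; a subject `N` never matches any pattern
#' position. Results are returned as a [GenomicRanges::GRanges] (1-based
#' coordinates, the Bioconductor convention) with metadata columns
#' `pattern_id` and `matched_seq` (the uppercase forward-strand slice).
#'
#' @param seq Subject sequence: character string, [Biostrings::DNAString],
#'   or a length-1 [Biostrings::DNAStringSet].
#' @param pattern A [MotifPattern][MotifPattern-class] or pattern string
#'   (parsed with [parsePattern()]).
#' @param seqId Sequence name used in the result (default `"seq"`, or the
#'   name of the `DNAStringSet` element).
#' @return `GRanges` of matches on the `+` strand; empty if none.
#' @examples
#' scanPattern("GATATACGCGTCGAGGTA", "SGSS")   # the CGCG of an MluI site
#' scanPattern("GGGGG", "SGSS")                # two overlapping matches
#' @seealso [scanBothStrands()], [scanTetrads()], [mergeSites()]
#' @export
scanPattern <- function(seq, pattern, seqId = NULL) {
    if (is.character(pattern))
        pattern <- parsePattern(pattern)
    stopifnot(is(pattern, "MotifPattern"))
    if (is.null(seqId))
        seqId <- if (is(seq, "DNAStringSet") && !is.null(names(seq)))
            names(seq)[1L] else "seq"
    ch <- .subjectChars(seq)
    off <- .matchOffsets(ch, pattern)
    .sitesGRanges(ch, off, length(pattern@baseSets), "+", pattern@id, seqId)
}

#' Scan both strands for a degenerate pattern
#'
#' Union of forward-strand matches of `pattern` and forward-strand
#' projections of reverse-strand matches (matches of the pattern's reverse
#' complement), each tagged with its strand and deduplicated on
#' (start, end, strand). For the tetrad consensus this realizes the
#' SGSS/SSCS duality: reverse-strand SGSS sites are exactly forward-strand
#' SSCS matches at the same coordinates.
#'
#' @inheritParams scanPattern
#' @return `GRanges` with strand `+` or `-`; `matched_seq` is always the
#'   forward-strand slice.
#' @examples
#' scanBothStrands("CCCC", "SGSS")   # one reverse-strand site (rc is GGGG)
#' scanBothStrands("CGCG", "SGSS")   # palindromic: both strands
#' @export
scanBothStrands <- function(seq, pattern, seqId = NULL) {
    if (is.character(pattern))
        pattern <- parsePattern(pattern)
    stopifnot(is(pattern, "MotifPattern"))
    if (is.null(seqId))
        seqId <- if (is(seq, "DNAStringSet") && !is.null(names(seq)))
            names(seq)[1L] else "seq"
    ch <- .subjectChars(seq)
    w <- length(pattern@baseSets)
    fwd <- .sitesGRanges(ch, .matchOffsets(ch, pattern), w, "+",
                         pattern@id, seqId)
    rcp <- reverseComplement(pattern)
    rev <- .sitesGRanges(ch, .matchOffsets(ch, rcp), w, "-",
                         pattern@id, seqId)
    out <- c(fwd, rev)
    key <- paste(start(out), end(out), strand(out))
    out <- out[!duplicated(key)]
    sort(out, ignore.strand = TRUE)
}

#' Scan for putative drug-binding GC tetrads
#'
#' Convenience wrapper scanning a sequence for a set of patterns on the
#' forward strand (default `{SGSS, SSCS}`, equivalent to SGSS on both
#' strands), optionally merging overlapping raw matches into discrete
#' sites.
#'
#' @inheritParams scanPattern
#' @param patterns List of [MotifPattern][MotifPattern-class] objects or
#'   pattern strings; default [oaPatterns()].
#' @param merge Logical; merge overlapping/bookended matches with
#'   [mergeSites()] (strand-agnostic). Default `FALSE`: raw matches.
#' @return `GRanges` of raw or merged sites.
#' @examples
#' scanTetrads("TTGGCGTTCCCGTT")
#' scanTetrads("GGGGG", merge = TRUE)
#' @export
scanTetrads <- function(seq, patterns = oaPatterns(), merge = FALSE,
                        seqId = NULL) {
    patterns <- lapply(patterns, function(p)
        if (is.character(p)) parsePattern(p) else p)
    hits <- lapply(patterns, function(p) scanPattern(seq, p, seqId = seqId))
    out <- do.call(c, unname(hits))
    out <- sort(out, ignore.strand = TRUE)
    if (merge) mergeSites(out, byStrand = FALSE) else out
}

#' Merge overlapping tetrad sites
#'
#' Unions overlapping or bookended sites into discrete regions (the view in
#' which a cluster of overlapping raw matches is one binding site). Sites
#' on different sequences are never merged; merging is idempotent and
#' preserves the set of covered bases. The merged `pattern_id` lists the
#' contributing pattern ids, comma-separated.
#'
#' @param sites `GRanges` of raw sites (as from [scanPattern()] or
#'   [scanTetrads()]).
#' @param byStrand Logical; if `TRUE` only sites on the same strand are
#'   merged, if `FALSE` (default) merging is strand-agnostic and the
#'   merged strand is `*` unless all contributors agree.
#' @return `GRanges` of merged regions with `pattern_id` and `n_raw`
#'   (number of contributing raw sites).
#' @examples
#' mergeSites(scanPattern("GGGGG", "SGSS"))   # [1,5] from [1,4]+[2,5]
#' @export
mergeSites <- function(sites, byStrand = FALSE) {
    stopifnot(is(sites, "GRanges"))
    if (!length(sites)) {
        out <- granges(sites)
        mcols(out)$pattern_id <- character(0)
        mcols(out)$n_raw <- integer(0)
        return(out)
    }
    red <- reduce(sites, with.revmap = TRUE, ignore.strand = !byStrand)
    rv <- mcols(red)$revmap
    mcols(red)$revmap <- NULL
    pid <- mcols(sites)$pattern_id
    if (is.null(pid))
        pid <- rep(NA_character_, length(sites))
    mcols(red)$pattern_id <- vapply(rv, function(i)
        paste(sort(unique(pid[i])), collapse = ","), character(1))
    mcols(red)$n_raw <- lengths(rv)
    if (!byStrand) {
        st <- vapply(rv, function(i) {
            s <- unique(as.character(strand(sites)[i]))
            if (length(s) == 1L) s else "*"
        }, character(1))
        strand(red) <- st
    }
    sort(red, ignore.strand = TRUE)
}
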