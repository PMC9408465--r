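#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table head
NULL

#' Read gene TSS anchors from BED6
#'
#' Anchors are 1 bp BED intervals: the BED `start` (0-based) is the TSS,
#' `name` the gene id, column 6 the strand. An optional sensitivity group
#' label (`I`/`II`/`III`) may be appended to the name as `gene|group`.
#'
#' @param path BED6 file path.
#' @return `GRanges` (width 1) with metadata columns `gene_id` and
#'   `group` (`NA` when absent).
#' @seealso [geneAnchors()], [makeWindows()]
#' @export
readAnchorsBed <- function(path) {
    .checkBedLines(path)
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) != 1L))
        stop("anchor BED intervals must have width 1 (a single TSS base)")
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
          else paste0("gene", seq_along(gr))
    parts <- strsplit(nm, "|", fixed = TRUE)
    geneAnchors(geneId = vapply(parts, `[`, "", 1L),
                seqId = as.character(GenomeInfoDb::seqnames(gr)),
                tss = start(gr) - 1L,
                strand = as.character(strand(gr)),
                group = vapply(parts, function(p)
                    if (length(p) > 1L) p[2L] else NA_character_, ""))
}

#' Read per-factor peak BED files
#'
#' @param paths Named character vector of BED paths; names are factor
#'   names (defaults to file base names).
#' @return Named list of `GRanges`, one per factor.
#' @export
readPeakBeds <- function(paths) {
    if (is.null(names(paths)))
        names(paths) <- sub("\\.bed$", "", basename(paths))
    lapply(paths, function(p) {
        .checkBedLines(p)
        rtracklayer::import(p, format = "BED")
    })
}

# Minimal structural validation so malformed lines are rejected with their
# line number before rtracklayer parses the file.
.checkBedLines <- function(path) {
    ln <- readLines(path)
    keep <- !grepl("^(#|track|browser)", ln) & nzchar(ln)
    for (i in which(keep)) {
        f <- strsplit(ln[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                         i, path))
        s <- suppressWarnings(as.numeric(f[2L]))
        e <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(s) || is.na(e) || s < 0 || e <= s)
            stop(sprintf(
                "malformed BED line %d in %s: need 0 <= start < end", i, path))
    }
    invisible(TRUE)
}

#' Export tetrad sites as BED6 plus a matched-sequence TSV
#'
#' BED output keeps the 0-based half-open convention; `score` is 0 and
#' `name` is the pattern id. If `tsv` is given, a tab-separated table with
#' the forward-strand matched sequence is written alongside.
#'
#' @param sites `GRanges` from [scanPattern()]/[scanTetrads()]/[mergeSites()].
#' @param bed Output BED path.
#' @param tsv Optional output TSV path.
#' @return Invisibly, the BED path.
#' @export
exportSitesBed <- function(sites, bed, tsv = NULL) {
    stopifnot(is(sites, "GRanges"))
    out <- sites
    mcols(out) <- NULL
    mcols(out)$name <- if (!is.null(mcols(sites)$pattern_id))
        mcols(sites)$pattern_id else "."
    mcols(out)$score <- 0L
    rtracklayer::export(out, bed, format = "BED")
    if (!is.null(tsv)) {
        df <- data.frame(seq_id = as.character(GenomeInfoDb::seqnames(sites)),
                         start = start(sites) - 1L, end = end(sites),
                         strand = as.character(strand(sites)),
                         pattern_id = mcols(sites)$pattern_id,
                         matched_seq = if (!is.null(mcols(sites)$matched_seq))
                             mcols(sites)$matched_seq else NA_character_)
        write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(bed)
}

#' Read or write a Ct table
#'
#' The documented layout is tab-separated with header columns `sample_id`,
#' `target`, `condition`, `time_h`, `replicate`, `ct` (ChIP tables add
#' `antibody`). `readCtTable()` validates the header and Ct range.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
readCtTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("sample_id", "target", "condition", "time_h", "replicate", "ct")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
    if (any(!is.finite(df$ct)))
        stop("non-finite Ct values in ", path)
    if (any(df$ct < 0 | df$ct > 50))
        warning("Ct values outside the usual 5-40 cycle range in ", path)
    df
}

#' @rdname readCtTable
#' @param df Ct table `data.frame`.
#' @export
writeCtTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
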