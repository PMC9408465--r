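#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom GenomeInfoDb seqlengths seqlevels
NULL

#' Construct gene TSS anchors
#'
#' An anchor is a gene's transcription start site with strand and an
#' optional transcriptional-sensitivity group label (`I` highly sensitive,
#' `II` averagely sensitive, `III` weakly sensitive).
#'
#' @param geneId Character vector of gene names.
#' @param seqId Contig name(s).
#' @param tss 0-based TSS position(s) (BED convention).
#' @param strand `"+"` or `"-"`.
#' @param group Optional group labels (`I`/`II`/`III`), `NA` if unknown.
#' @return `GRanges` of width-1 anchors with metadata columns `gene_id`,
#'   `tss` (0-based) and `group`.
#' @examples
#' geneAnchors("MYC", "chr8", 127735434, "+", group = "I")
#' @export
geneAnchors <- function(geneId, seqId, tss, strand, group = NA_character_) {
    stopifnot(all(tss >= 0), all(strand %in% c("+", "-")))
    n <- length(geneId)
    gr <- GRanges(seqnames = rep_len(seqId, n),
                  ranges = IRanges(start = tss + 1L, width = 1L),
                  strand = rep_len(strand, n))
    mcols(gr)$gene_id <- geneId
    mcols(gr)$tss <- as.integer(tss)
    mcols(gr)$group <- rep_len(as.character(group), n)
    gr
}

#' Build strand-aware promoter windows around TSSs
#'
#' Returns the genomic interval `[tss - W, tss + W)` (0-based half-open)
#' for each anchor, clipped at contig bounds when lengths are known. The
#' default half-width of 2500 bp matches the promoter region analyzed for
#' tetrad and transcription-factor mapping.
#'
#' @param anchors `GRanges` from [geneAnchors()] or [readAnchorsBed()].
#' @param halfWidth Window half-width W in bp (> 0); default 2500.
#' @param seqlengths Optional named vector of contig lengths for clipping;
#'   a TSS outside its contig is an error naming the gene.
#' @return `GRanges` of windows carrying the anchor metadata plus a
#'   `clipped` flag.
#' @examples
#' a <- geneAnchors("g1", "chr1", 10000, "+")
#' makeWindows(a)                       # [7500, 12500) -> 1-based 7501-12500
#' @export
makeWindows <- function(anchors, halfWidth = 2500, seqlengths = NULL) {
    stopifnot(is(anchors, "GRanges"))
    if (!is.numeric(halfWidth) || length(halfWidth) != 1L || halfWidth <= 0)
        stop("'halfWidth' must be a single positive number")
    tss <- mcols(anchors)$tss
    if (is.null(tss))
        tss <- start(anchors) - 1L
    s0 <- pmax(tss - halfWidth, 0)
    e0 <- tss + halfWidth
    clipped <- s0 != tss - halfWidth
    if (!is.null(seqlengths)) {
        sq <- as.character(seqnames(anchors))
        len <- seqlengths[sq]
        if (any(is.na(len)))
            stop("no contig length for: ",
                 paste(unique(sq[is.na(len)]), collapse = ", "))
        out <- tss >= len | tss < 0
        if (any(out))
            stop("TSS outside contig bounds for gene(s): ",
                 paste(mcols(anchors)$gene_id[out], collapse = ", "))
        clipped <- clipped | e0 > len
        e0 <- pmin(e0, len)
    }
    win <- GRanges(seqnames = seqnames(anchors),
                   ranges = IRanges(start = s0 + 1L, end = e0),
                   strand = strand(anchors))
    mcols(win) <- mcols(anchors)
    mcols(win)$clipped <- clipped
    win
}

#' Map genomic sites to TSS-relative coordinates
#'
#' Converts genomic intervals to transcription-oriented, TSS-relative
#' coordinates (negative = upstream, as in a d(SGSS) promoter map). For a
#' minus-strand gene the axis is mirrored so that it still points in the
#' direction of transcription. Sites wholly outside the `[-W, +W)` window
#' are dropped; partial overlaps are clipped.
#'
#' @param sites `GRanges` of sites (tetrads or peaks) on the anchor's
#'   contig; a contig mismatch is an error.
#' @param anchor A single-gene anchor (`GRanges` of length 1).
#' @param halfWidth Window half-width W; default 2500.
#' @param source Label for the site class (`"tetrad"` or `"peak"`).
#' @param label Optional per-site label; defaults to the `pattern_id` or
#'   `name` metadata column when present.
#' @return `data.frame` with `gene_id`, `rel_start`, `rel_end` (0-based
#'   half-open on the relative axis), `source`, `label`, `clipped`.
#' @examples
#' a <- geneAnchors("g1", "chr1", 10000, "+")
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10301, 10304))
#' toRelative(s, a)   # rel [300, 304)
#' @export
toRelative <- function(sites, anchor, halfWidth = 2500, source = "tetrad",
                       label = NULL) {
    stopifnot(is(sites, "GRanges"), is(anchor, "GRanges"),
              length(anchor) == 1L)
    if (length(sites) &&
        !all(as.character(seqnames(sites)) ==
             as.character(seqnames(anchor))))
        stop("site contig does not match anchor contig for gene ",
             mcols(anchor)$gene_id %||% "(unnamed)")
    tss <- mcols(anchor)$tss %||% (start(anchor) - 1L)
    s0 <- start(sites) - 1L
    e0 <- end(sites)
    if (as.character(strand(anchor)) == "+") {
        rs <- s0 - tss; re <- e0 - tss
    } else {
        rs <- tss - e0; re <- tss - s0
    }
    if (is.null(label)) {
        label <- mcols(sites)$pattern_id %||% mcols(sites)$name %||%
            rep(NA_character_, length(sites))
    }
    keep <- re > -halfWidth & rs < halfWidth
    rs <- rs[keep]; re <- re[keep]; label <- label[keep]
    clip <- rs < -halfWidth | re > halfWidth
    rs <- pmax(rs, -halfWidth)
    re <- pmin(re, halfWidth)
    data.frame(gene_id = rep(mcols(anchor)$gene_id %||% NA_character_,
                             length(rs)),
               rel_start = as.integer(rs), rel_end = as.integer(re),
               source = rep(source, length(rs)), label = label,
               clipped = clip, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlay transcription-factor peaks on promoter windows
#'
#' Builds the gene-by-factor presence matrix: `TRUE` when any peak of a
#' factor intersects the gene's window by at least 1 bp (half-open
#' semantics: a peak abutting the window end is absent). The result is
#' invariant under the record order of the peak files.
#'
#' @param windows `GRanges` from [makeWindows()] (metadata `gene_id`).
#' @param peaks Named list of `GRanges` (one per factor), e.g. from
#'   [readPeakBeds()].
#' @return Logical matrix, rows = genes, columns = factors.
#' @seealso [classifyFactors()]
#' @export
overlayPeaks <- function(windows, peaks) {
    stopifnot(is(windows, "GRanges"), is.list(peaks))
    if (is.null(names(peaks)) || any(!nzchar(names(peaks))))
        stop("'peaks' must be a named list (factor names)")
    genes <- mcols(windows)$gene_id %||%
        paste0("gene", seq_along(windows))
    pres <- vapply(peaks, function(p)
        IRanges::overlapsAny(windows, p, ignore.strand = TRUE),
        logical(length(windows)))
    pres <- matrix(pres, nrow = length(windows),
                   dimnames = list(genes, names(peaks)))
    pres
}

#' Classify a factor by association with gene sensitivity groups
#'
#' Applies the dichotomy observed for promoter-proximal factor binding:
#' a factor is `absent` when it binds no analyzed gene;
#' `sensitive_restricted` when it binds at least one drug-attenuated gene
#' (groups I or II) and no weakly sensitive gene (group III);
#' `ubiquitous` when it binds a majority of genes including at least one
#' group III gene; anything else is reported as `other` rather than being
#' forced into a category.
#'
#' @param presence Logical vector (one entry per gene).
#' @param groups Character vector of group labels (`I`/`II`/`III`),
#'   aligned with `presence`; an unlabeled gene is an error.
#' @param majority Fraction of genes defining "majority"; default 0.5.
#' @return Character scalar: `absent`, `sensitive_restricted`,
#'   `ubiquitous`, or `other`.
#' @export
classifyFactor <- function(presence, groups, majority = 0.5) {
    stopifnot(is.logical(presence), length(presence) == length(groups))
    bad <- is.na(groups) | !groups %in% c("I", "II", "III")
    if (any(bad))
        stop("unlabeled or invalid group for gene(s): ",
             paste(names(presence)[bad] %||% which(bad), collapse = ", "))
    if (!any(presence))
        return("absent")
    inSens <- any(presence & groups %in% c("I", "II"))
    inIII <- any(presence & groups == "III")
    if (inSens && !inIII)
        return("sensitive_restricted")
    if (mean(presence) >= majority && inIII)
        return("ubiquitous")
    "other"
}

#' @rdname classifyFactor
#' @param presenceMatrix Logical gene-by-factor matrix from
#'   [overlayPeaks()].
#' @return For `classifyFactors()`: `data.frame` with one row per factor
#'   (`factor`, `call`, `n_present`, `n_group_III`).
#' @export
classifyFactors <- function(presenceMatrix, groups, majority = 0.5) {
    stopifnot(is.matrix(presenceMatrix))
    calls <- vapply(colnames(presenceMatrix), function(f)
        classifyFactor(stats::setNames(presenceMatrix[, f],
                                       rownames(presenceMatrix)),
                       groups, majority = majority), character(1))
    data.frame(factor = colnames(presenceMatrix), call = unname(calls),
               n_present = unname(colSums(presenceMatrix)),
               n_group_III = unname(colSums(
                   presenceMatrix[groups == "III", , drop = FALSE])),
               stringsAsFactors = FALSE)
}
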