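test_that("promoter windows are [tss-W, tss+W) with clipping", {
    a <- geneAnchors("g1", "chr1", 10000, "+")
    w <- makeWindows(a, 2500)
    expect_equal(BiocGenerics::start(w), 7501L)   # 0-based [7500, 12500)
    expect_equal(BiocGenerics::end(w), 12500L)
    expect_false(S4Vectors::mcols(w)$clipped)

    a2 <- geneAnchors("g2", "chrS", 1000, "+")
    w2 <- makeWindows(a2, 2500, seqlengths = c(chrS = 5000))
    expect_equal(BiocGenerics::start(w2), 1L)     # clipped at contig start
    expect_equal(BiocGenerics::end(w2), 3500L)
    expect_true(S4Vectors::mcols(w2)$clipped)

    expect_error(makeWindows(a, 0), "positive")
    a3 <- geneAnchors("g3", "chrS", 6000, "+")
    expect_error(makeWindows(a3, 100, seqlengths = c(chrS = 5000)), "g3")
})

test_that("TSS-relative mapping is strand-aware and mirrors correctly", {
    aPlus <- geneAnchors("gp", "chr1", 10000, "+")
    aMinus <- geneAnchors("gm", "chr1", 10000, "-")
    sPlus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10301, 10304))
    sMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9697, 9700))

    rp <- toRelative(sPlus, aPlus)
    expect_equal(rp$rel_start, 300L)
    expect_equal(rp$rel_end, 304L)
    rm <- toRelative(sMinus, aMinus)
    expect_equal(rm$rel_start, 300L)
    expect_equal(rm$rel_end, 304L)

    far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 20004))
    expect_equal(nrow(toRelative(far, aPlus)), 0L)

    wrong <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 4))
    expect_error(toRelative(wrong, aPlus), "contig")

    # strand involution: mapping a minus-strand relative interval back to
    # genomic coordinates recovers the original interval
    set.seed(3)
    for (i in 1:50) {
        st <- sample(8000:11900, 1)
        en <- st + sample(1:100, 1)
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, en))
        r <- toRelative(gr, aMinus, halfWidth = 2500)
        if (!nrow(r) || r$clipped) next
        backStart0 <- 10000 - r$rel_end     # invert the minus-strand map
        backEnd0 <- 10000 - r$rel_start
        expect_equal(backStart0 + 1L, st)
        expect_equal(backEnd0, en)
    }
})

test_that("relative sites always satisfy window containment", {
    set.seed(9)
    for (i in 1:100) {
        strand <- sample(c("+", "-"), 1)
        a <- geneAnchors("g", "c", 5000, strand)
        st <- sample(1:12000, 1)
        gr <- GenomicRanges::GRanges("c",
            IRanges::IRanges(st, st + sample(1:4000, 1)))
        r <- toRelative(gr, a, halfWidth = 2500)
        if (!nrow(r)) next
        expect_true(all(r$rel_start >= -2500 & r$rel_end <= 2500 &
                        r$rel_start < r$rel_end))
    }
})

test_that("peak overlay uses half-open >=1 bp intersection semantics", {
    a <- geneAnchors(c("g1", "g2", "g3"), "chr1",
                     c(10000, 30000, 50000), "+",
                     group = c("I", "II", "III"))
    w <- makeWindows(a, 2500)
    # g1 window is [7500, 12500): a peak [12500,12600) abuts, no overlap
    peaks <- list(
        fA = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(12501, 29001), c(12600, 31000))),
        fB = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(7000, 47501), c(13000, 47600))))
    pres <- overlayPeaks(w, peaks)
    expect_identical(pres, matrix(c(FALSE, TRUE, FALSE,
                                    TRUE, FALSE, TRUE),
                                  nrow = 3,
                                  dimnames = list(c("g1", "g2", "g3"),
                                                  c("fA", "fB"))))
    # invariance under record order
    peaksShuffled <- lapply(peaks, function(p) p[rev(seq_along(p))])
    expect_identical(overlayPeaks(w, peaksShuffled), pres)
})

test_that("factor association calls follow the sensitivity dichotomy", {
    groups <- c(g1 = "I", g2 = "I", g3 = "II", g4 = "III", g5 = "III")
    g <- unname(groups)
    expect_equal(classifyFactor(rep(FALSE, 5), g), "absent")
    expect_equal(classifyFactor(rep(TRUE, 5), g), "ubiquitous")
    expect_equal(classifyFactor(c(TRUE, TRUE, FALSE, FALSE, FALSE), g),
                 "sensitive_restricted")
    # present only in a minority that includes group III -> other
    expect_equal(classifyFactor(c(FALSE, FALSE, FALSE, TRUE, FALSE), g),
                 "other")
    # majority threshold is configurable
    expect_equal(classifyFactor(c(TRUE, TRUE, FALSE, TRUE, FALSE), g,
                                majority = 0.6), "ubiquitous")
    expect_error(classifyFactor(rep(TRUE, 5), c(g[-5], NA)), "unlabeled")
    expect_error(classifyFactor(rep(TRUE, 5), c(g[-5], "IV")), "unlabeled")
})

test_that("anchor and peak BED input validates structure", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t9999\t10000\tgeneA|I\t0\t+",
                 "chr1\t29999\t30000\tgeneB|III\t0\t-"), bed)
    a <- readAnchorsBed(bed)
    expect_equal(S4Vectors::mcols(a)$gene_id, c("geneA", "geneB"))
    expect_equal(S4Vectors::mcols(a)$tss, c(9999L, 29999L))
    expect_equal(S4Vectors::mcols(a)$group, c("I", "III"))
    expect_equal(as.character(BiocGenerics::strand(a)), c("+", "-"))

    bad <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200\tp1", "chr1\t300\t250\tp2"), bad)
    expect_error(readPeakBeds(c(f = bad)), "line 2")
    unlink(c(bed, bad))
})
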