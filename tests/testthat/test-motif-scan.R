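test_that("degenerate patterns parse to the right base sets", {
    p <- parsePattern("SGSS")
    expect_s4_class(p, "MotifPattern")
    expect_equal(patternString(p), "SGSS")
    expect_equal(baseSets(p),
                 list(c("G", "C"), "G", c("G", "C"), c("G", "C")))
    ob <- obligatePositions(p)
    expect_length(ob, 1L)
    expect_equal(ob[[1]]$position, 2L)
    expect_equal(ob[[1]]$base, "G")

    q <- parsePattern("ACGT")
    expect_equal(lengths(baseSets(q)), rep(1L, 4))

    expect_error(parsePattern("SXSS"), "invalid IUPAC code 'X' at position 2")
    expect_error(parsePattern(""), "non-empty")
    # lower case normalized
    expect_equal(baseSets(parsePattern("sgss")), baseSets(p))
})

test_that("reverse complement of SGSS is SSCS and involutes", {
    p <- parsePattern("SGSS")
    rc <- reverseComplement(p)
    expect_equal(patternString(rc), "SSCS")
    expect_equal(patternString(reverseComplement(rc)), "SGSS")
    expect_equal(obligatePositions(rc)[[1]]$position, 3L)
    expect_equal(obligatePositions(rc)[[1]]$base, "C")
})

test_that("forward scan finds all and only the matching offsets", {
    # the published forward primer: its only tetrad is the MluI-internal CGCG
    hits <- scanPattern("GATATACGCGTCGAGGTA", "SGSS")
    expect_length(hits, 1L)
    expect_equal(BiocGenerics::start(hits), 7L)   # 0-based [6,10)
    expect_equal(BiocGenerics::end(hits), 10L)
    expect_equal(S4Vectors::mcols(hits)$matched_seq, "CGCG")

    expect_length(scanPattern("AAAAAA", "SGSS"), 0L)

    hits <- scanPattern("GGGGG", "SGSS")          # overlapping matches
    expect_equal(BiocGenerics::start(hits), c(1L, 2L))

    # empty and too-short subjects give empty results, not errors
    expect_length(scanPattern("", "SGSS"), 0L)
    expect_length(scanPattern("GG", "SGSS"), 0L)
    # subject N never matches; case-insensitive subjects
    expect_length(scanPattern("GNGG", "SGSS"), 0L)
    expect_length(scanPattern("gggg", "SGSS"), 1L)
    expect_error(scanPattern("GGXG", "SGSS"), "invalid base 'X'")
})

test_that("scan agrees with a brute-force matcher on random sequences", {
    set.seed(42)
    pats <- c("SGSS", "SSCS", "RYSW", "NGCN")
    for (i in 1:300) {
        s <- randomDna(sample(0:200, 1), gc = runif(1, 0.2, 0.8),
                       withN = TRUE)
        p <- sample(pats, 1)
        got <- BiocGenerics::start(scanPattern(s, p))
        expect_identical(got, bruteScan(s, p))
    }
})

test_that("scan agrees with Biostrings degenerate matching", {
    set.seed(7)
    for (i in 1:50) {
        s <- randomDna(sample(10:150, 1), gc = 0.6)
        hits <- scanPattern(s, "SGSS")
        bs <- Biostrings::matchPattern("SGSS", Biostrings::DNAString(s),
                                       fixed = FALSE)
        expect_identical(BiocGenerics::start(hits),
                         as.integer(BiocGenerics::start(bs)))
    }
})

test_that("both-strand scanning realizes the SGSS/SSCS duality", {
    # CCCC only matches on the reverse strand (rc is GGGG)
    h <- scanBothStrands("CCCC", "SGSS")
    expect_length(h, 1L)
    expect_equal(as.character(BiocGenerics::strand(h)), "-")
    expect_equal(S4Vectors::mcols(h)$matched_seq, "CCCC")

    # CGCG is its own reverse complement: both strands at [0,4)
    h <- scanBothStrands("CGCG", "SGSS")
    expect_length(h, 2L)
    expect_setequal(as.character(BiocGenerics::strand(h)), c("+", "-"))
    expect_equal(unique(BiocGenerics::start(h)), 1L)

    expect_length(scanBothStrands("ATATAT", "SGSS"), 0L)

    set.seed(11)
    for (i in 1:200) {
        s <- randomDna(sample(4:120, 1), gc = runif(1, 0.3, 0.7))
        # reverse-strand SGSS == forward-strand SSCS at identical intervals
        bh <- scanBothStrands(s, "SGSS")
        minus <- bh[BiocGenerics::strand(bh) == "-"]
        sscs <- scanPattern(s, "SSCS")
        expect_identical(BiocGenerics::start(minus),
                         BiocGenerics::start(sscs))
        # strand symmetry: reverse-strand sites = mirrored forward sites
        # of the pattern on the reverse complement
        n <- nchar(s)
        rcHits <- BiocGenerics::start(scanPattern(revComp(s), "SGSS"))
        mirrored <- sort(n - (rcHits + 4L - 1L) + 1L)
        expect_identical(BiocGenerics::start(minus), mirrored)
    }
})

test_that("merging unions overlapping and bookended sites per sequence", {
    m <- mergeSites(scanPattern("GGGGG", "SGSS"))
    expect_length(m, 1L)
    expect_equal(BiocGenerics::start(m), 1L)
    expect_equal(BiocGenerics::end(m), 5L)
    expect_equal(S4Vectors::mcols(m)$n_raw, 2L)

    one <- scanPattern("TTGGGGTT", "SGSS")
    expect_equal(BiocGenerics::start(mergeSites(one)),
                 BiocGenerics::start(one))

    two <- scanTetrads("GGGGTTTTTTGGGG", patterns = list("SGSS"))
    expect_length(mergeSites(two), 2L)

    # never merge across sequences
    gr <- suppressWarnings(c(scanPattern("GGGG", "SGSS", seqId = "a"),
                             scanPattern("GGGG", "SGSS", seqId = "b")))
    expect_length(mergeSites(gr), 2L)

    # idempotence + coverage preservation on random inputs
    set.seed(5)
    for (i in 1:100) {
        s <- randomDna(sample(20:150, 1), gc = 0.7)
        raw <- scanTetrads(s)
        if (!length(raw)) next
        m1 <- mergeSites(raw)
        m2 <- mergeSites(m1)
        expect_equal(IRanges::ranges(m1), IRanges::ranges(m2))
        cov <- unique(unlist(mapply(seq, BiocGenerics::start(raw),
                                    BiocGenerics::end(raw),
                                    SIMPLIFY = FALSE)))
        expect_equal(sum(BiocGenerics::width(m1)), length(cov))
        # interval union oracle
        u <- unionIntervals(BiocGenerics::start(raw),
                            BiocGenerics::end(raw))
        expect_equal(BiocGenerics::start(m1), unname(u[, "start"]))
        expect_equal(BiocGenerics::end(m1), unname(u[, "end"]))
    }
})

test_that("site BED/TSV export round-trips coordinates 0-based half-open", {
    sites <- scanTetrads("TTGGCGTTCCCGTT", seqId = "chrT")
    bed <- tempfile(fileext = ".bed")
    tsv <- tempfile(fileext = ".tsv")
    exportSitesBed(sites, bed, tsv)
    lines <- strsplit(readLines(bed), "\t")
    expect_equal(as.integer(vapply(lines, `[`, "", 2)),
                 BiocGenerics::start(sites) - 1L)
    expect_equal(as.integer(vapply(lines, `[`, "", 3)),
                 BiocGenerics::end(sites))
    df <- read.delim(tsv)
    expect_equal(df$matched_seq, S4Vectors::mcols(sites)$matched_seq)
    unlink(c(bed, tsv))
})
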