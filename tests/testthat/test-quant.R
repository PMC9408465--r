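makeCt <- function(targetCt, normCt, target = "GENE", reps = 1) {
    # targetCt/normCt: named numeric vectors "condition@time" -> mean Ct
    rows <- list()
    for (k in names(targetCt)) {
        ct <- strsplit(k, "@")[[1]]
        for (r in seq_len(reps)) {
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = paste(k, r), target = c(target, "RPLP0"),
                condition = ct[1], time_h = as.numeric(ct[2]),
                replicate = r, ct = c(targetCt[[k]], normCt[[k]]))
        }
    }
    do.call(rbind, rows)
}

test_that("delta-delta Ct reproduces the closed-form examples", {
    ct <- makeCt(c("untreated@0" = 20, "OA@3" = 23),
                 c("untreated@0" = 15, "OA@3" = 15))
    res <- suppressWarnings(deltaDeltaCt(ct, "GENE"))
    expect_equal(res$ddct[res$condition == "OA"], 3)
    expect_equal(res$fold_change[res$condition == "OA"], 0.125)
    expect_equal(res$fold_change[res$condition == "untreated"], 1)

    # treated == untreated exactly -> fold change 1
    ct2 <- makeCt(c("untreated@0" = 21, "OA@3" = 21),
                  c("untreated@0" = 16, "OA@3" = 16))
    res2 <- suppressWarnings(deltaDeltaCt(ct2, "GENE"))
    expect_equal(res2$fold_change, c(1, 1))

    # one Ct cycle == exactly two-fold, everywhere
    ct3 <- makeCt(c("untreated@0" = 20, "OA@1" = 21, "OA@3" = 22),
                  c("untreated@0" = 15, "OA@1" = 15, "OA@3" = 15))
    res3 <- suppressWarnings(deltaDeltaCt(ct3, "GENE"))
    expect_equal(sort(res3$fold_change, decreasing = TRUE), c(1, 0.5, 0.25))
})

test_that("delta-delta Ct validates its inputs", {
    ct <- makeCt(c("untreated@0" = 20, "OA@3" = 23),
                 c("untreated@0" = 15, "OA@3" = 15))
    expect_error(deltaDeltaCt(ct, "GENE", normalizer = "GAPDH"),
                 "normalizer")
    expect_error(suppressWarnings(
        deltaDeltaCt(ct, "GENE", referenceCondition = "mock")),
        "reference")
    noNorm <- ct[!(ct$target == "RPLP0" & ct$condition == "OA"), ]
    expect_error(suppressWarnings(deltaDeltaCt(noNorm, "GENE")), "missing")
    expect_warning(deltaDeltaCt(ct, "GENE"), "replicates")
    # single replicate: result produced, SD undefined
    res <- suppressWarnings(deltaDeltaCt(ct, "GENE"))
    expect_true(all(is.na(res$sd_log2)))
})

test_that("chain consistency holds through a shared reference", {
    set.seed(31)
    for (i in 1:20) {
        cts <- round(runif(3, 18, 30), 2)
        ct <- makeCt(c("untreated@0" = cts[1], "OA@3" = cts[2],
                       "OA@6" = cts[3]),
                     c("untreated@0" = 15, "OA@3" = 15, "OA@6" = 15),
                     reps = 3)
        res <- deltaDeltaCt(ct, "GENE")
        fcAB <- res$fold_change[res$time_h == 3]
        fcAC <- res$fold_change[res$time_h == 6]
        # re-reference at 3 h: fold change 3h -> 6h
        res2 <- deltaDeltaCt(ct, "GENE", referenceCondition = "OA",
                             referenceTime = 3)
        fcBC <- res2$fold_change[res2$time_h == 6]
        expect_equal(fcAC, fcAB * fcBC, tolerance = 1e-9)
    }
})

test_that("percent of input follows the dilution-adjusted formula", {
    expect_identical(percentInput(25, 25, 1), 100)
    expect_equal(percentInput(27, 25, 1), 25)
    expect_equal(percentInput(22, 25, 0.01), 100 * 2^(25 - log2(100) - 22))
    expect_equal(percentInput(22, 25, 0.01), 8, tolerance = 1e-3)
    expect_error(percentInput(20, 20, 0), "inputFraction")
    expect_error(percentInput(20, 20, 1.5), "inputFraction")
    expect_error(percentInput(20, 20, -1), "inputFraction")
})

test_that("ChIP tables collapse to percent-input and normalize to 0 h", {
    chip <- data.frame(
        sample_id = "s", target = "prom",
        antibody = rep(c("RNAPII", "input"), each = 2),
        condition = "x", time_h = rep(c(0, 3), 2), replicate = 1,
        ct = c(25, 26, 25, 25))  # 0h: equal Cts; 3h: IP 1 cycle later
    res <- chipPercentInput(chip, inputFraction = 1)
    expect_equal(res$percent_input[res$time_h == 0], 100)
    expect_equal(res$percent_input[res$time_h == 3], 50)
    norm <- normalizeToT0(res)
    expect_identical(norm$relative_to_t0[norm$time_h == 0], 100)
    expect_equal(norm$relative_to_t0[norm$time_h == 3], 50)

    expect_error(chipPercentInput(chip[chip$antibody != "input", ], 1),
                 "input")
    expect_error(normalizeToT0(data.frame(time_h = 3, percent_input = 2)),
                 "0 h")
    expect_error(normalizeToT0(data.frame(time_h = c(0, 3),
                                          percent_input = c(0, 2))),
                 "non-positive")
    # constant series -> all 100
    const <- data.frame(time_h = c(0, 1, 3), percent_input = c(4, 4, 4))
    expect_equal(normalizeToT0(const)$relative_to_t0, c(100, 100, 100))
})

test_that("Ct tables round-trip through TSV with header validation", {
    cfg <- simConfig(seed = 20, nGenes = 2, geneIds = c("a", "b"),
                     groups = c("I", "III"))
    tabs <- simCtTables(cfg)
    f <- tempfile(fileext = ".tsv")
    writeCtTable(tabs$qpcr, f)
    back <- readCtTable(f)
    expect_equal(back$ct, tabs$qpcr$ct)
    expect_equal(back$target, tabs$qpcr$target)
    writeCtTable(tabs$qpcr[, names(tabs$qpcr) != "ct"], f)
    expect_error(readCtTable(f), "missing column")
    unlink(f)
})

test_that("noiseless synthetic tables are recovered exactly", {
    cfg <- simConfig(seed = 2, nGenes = 3, ctSigma = 0, jitterSd = 0)
    tabs <- simCtTables(cfg)
    for (g in cfg$geneIds) {
        est <- deltaDeltaCt(tabs$qpcr[tabs$qpcr$target %in%
                                      c(g, "RPLP0"), ], g)
        truth <- tabs$qpcrTruth[tabs$qpcrTruth$gene_id == g, ]
        est <- est[match(truth$time_h, est$time_h), ]
        expect_equal(log2(est$fold_change), truth$log2_fc_true,
                     tolerance = 1e-9)
    }
    chip <- chipPercentInput(tabs$chip, cfg$inputFraction)
    truth <- tabs$chipTruth
    key <- paste(chip$target, chip$antibody, chip$time_h)
    tkey <- paste(truth$target, truth$antibody, truth$time_h)
    expect_equal(chip$percent_input, truth$percent_input_true[match(key, tkey)],
                 tolerance = 1e-9)
})

test_that("fold-change estimates are unbiased on noisy triplicates", {
    cfg <- simConfig(seed = 4, nGenes = 60, geneIds = sprintf("g%02d", 1:60),
                     groups = rep_len(c("I", "II", "III"), 60),
                     ctSigma = 0.2, replicates = 3)
    tabs <- simCtTables(cfg)
    est <- estimateCohortFC(tabs$qpcr, cfg$geneIds, cfg$timesH)
    truth <- tabs$qpcrTruth
    key <- paste(est$gene_id, est$time_h)
    tkey <- paste(truth$gene_id, truth$time_h)
    err <- log2(est$fold_change) - truth$log2_fc_true[match(key, tkey)]
    # ddCt noise SD is 2*sigma/sqrt(3) ~ 0.23; the planted truth must sit
    # well inside a 3-sigma envelope of each estimate
    expect_lt(abs(mean(err)), 0.1)
    expect_lt(max(abs(err)), 3 * 2 * cfg$ctSigma / sqrt(3) * 1.5)
})
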