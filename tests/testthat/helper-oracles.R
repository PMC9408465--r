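# Independent oracles and fixture builders, deliberately naive so they
# share no code path with the package implementation.

IUPAC_ORACLE <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# position-by-position brute-force matcher; returns 1-based start positions
bruteScan <- function(seq, patternText) {
    ch <- strsplit(toupper(seq), "")[[1]]
    sym <- strsplit(toupper(patternText), "")[[1]]
    m <- length(sym)
    n <- length(ch)
    if (n < m) return(integer(0))
    starts <- integer(0)
    for (i in seq_len(n - m + 1L)) {
        ok <- TRUE
        for (j in seq_len(m)) {
            if (!(ch[i + j - 1L] %in% IUPAC_ORACLE[[sym[j]]])) {
                ok <- FALSE
                break
            }
        }
        if (ok) starts <- c(starts, i)
    }
    starts
}

revComp <- function(s)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                   collapse = ""))

randomDna <- function(n, gc = 0.5, withN = FALSE) {
    alpha <- c("A", "C", "G", "T")
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    if (withN) {
        alpha <- c(alpha, "N")
        prob <- c(prob * 0.98, 0.02)
    }
    paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

# interval union oracle on (start, end) 1-based closed pairs
unionIntervals <- function(st, en) {
    o <- order(st, en)
    st <- st[o]; en <- en[o]
    outS <- st[1]; outE <- en[1]
    for (k in seq_along(st)[-1]) {
        if (st[k] <= outE[length(outE)] + 1L)
            outE[length(outE)] <- max(outE[length(outE)], en[k])
        else {
            outS <- c(outS, st[k]); outE <- c(outE, en[k])
        }
    }
    cbind(start = outS, end = outE)
}

# estimate per-gene fold-change series from a simulated qPCR table;
# each gene is quantified against the normalizer wells of its own plate
# (rows sharing its sample_id prefix)
estimateCohortFC <- function(qpcr, genes, timesH) {
    rows <- lapply(genes, function(g) {
        plate <- qpcr[startsWith(qpcr$sample_id, paste0(g, "_")), ]
        est <- suppressWarnings(deltaDeltaCt(plate, g))
        est <- est[est$time_h %in% timesH, ]
        data.frame(gene_id = g, time_h = est$time_h,
                   fold_change = est$fold_change)
    })
    do.call(rbind, rows)
}
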