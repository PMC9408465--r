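#' In-silico PCR product of a primer pair
#'
#' Locates a forward primer on the plus strand and a reverse primer on the
#' minus strand (i.e. the reverse complement of the reverse primer on the
#' plus strand) of a template, and returns the amplicon they delimit —
#' the worked example being the 144 bp minimal-promoter fragment amplified
#' by the cmvF/cmvR pair for band-shift and footprinting assays.
#'
#' @param template Template sequence (character, [Biostrings::DNAString]
#'   or length-1 [Biostrings::DNAStringSet]).
#' @param forward,reverse Primer sequences, 5' to 3' (character or
#'   `DNAString`). Exact matching, case-insensitive.
#' @return A list with `start`, `end` (1-based inclusive template
#'   coordinates of the product), `length` (bp) and `product`
#'   (`DNAString` of the plus-strand amplicon).
#' @examples
#' p <- cmvPrimers()
#' pcrProduct(cmvSyntheticPromoter(), p["cmvF"], p["cmvR"])$length
#' @export
pcrProduct <- function(template, forward, reverse) {
    ch <- paste(.subjectChars(template), collapse = "")
    fwd <- paste(.subjectChars(forward), collapse = "")
    rev <- paste(.subjectChars(reverse), collapse = "")
    revRc <- as.character(reverseComplement(DNAString(rev)))
    fhit <- gregexpr(fwd, ch, fixed = TRUE)[[1L]]
    rhit <- gregexpr(revRc, ch, fixed = TRUE)[[1L]]
    if (fhit[1L] == -1L)
        stop("forward primer not found on the template plus strand")
    if (rhit[1L] == -1L)
        stop("reverse primer not found on the template minus strand")
    fstart <- as.integer(fhit[1L])
    rend <- as.integer(rhit[length(rhit)]) + nchar(revRc) - 1L
    rok <- rhit[rhit + nchar(revRc) - 1L >= fstart + nchar(fwd) - 1L]
    if (!length(rok))
        stop("primers do not face each other: no product")
    rend <- as.integer(rok[1L]) + nchar(revRc) - 1L
    list(start = fstart, end = rend, length = rend - fstart + 1L,
         product = DNAString(substr(ch, fstart, rend)))
}

#' Synthetic stand-in for the minimal CMV promoter construct
#'
#' A synthetic 204 bp sequence emulating a minimal CMV
#' promoter construct used for tetrad mutagenesis: the cmvF/cmvR
#' primer pair delimits a 144 bp core, the forward primer carries the MluI
#' cloning site (`ACGCGT`, whose internal `CGCG` tetrad is left intact in
#' the mutant design), and five isolated GC tetrads (SGSS/SSCS) sit on an
#' A/T-rich background between the primers. It is a constructed stand-in,
#' not a real vector sequence; the structural facts it encodes (a
#' 144 bp amplicon; five mutagenized tetrads plus one protected cloning
#' site) mirror the described construct.
#'
#' @return A named [Biostrings::DNAStringSet] of length 1
#'   (`"CMVwt_synthetic"`).
#' @examples
#' cmvSyntheticPromoter()
#' @export
cmvSyntheticPromoter <- function() {
    fa <- system.file("extdata", "cmv_minimal_promoter_synthetic.fa",
                      package = "GCtetrads", mustWork = TRUE)
    readDNAStringSet(fa)
}

#' @rdname cmvSyntheticPromoter
#' @details `cmvPrimers()` returns the primer pair used to
#'   amplify the 144 bp promoter fragment (forward primer `cmvF`, reverse
#'   primer `cmvR`, both 5' to 3').
#' @export
cmvPrimers <- function() {
    c(cmvF = "GATATACGCGTCGAGGTA", cmvR = "GTACCAGGAGGCTGGAT")
}

#' @rdname cmvSyntheticPromoter
#' @details `mluIProtected()` returns the protected MluI cloning-site
#'   interval (`ACGCGT`) of the synthetic construct as an
#'   [IRanges::IRanges] in 1-based coordinates of the returned sequence.
#' @export
mluIProtected <- function() {
    ch <- paste(.subjectChars(cmvSyntheticPromoter()), collapse = "")
    hit <- regexpr("ACGCGT", ch, fixed = TRUE)
    stopifnot(hit != -1L)
    IRanges(start = as.integer(hit), width = 6L)
}
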