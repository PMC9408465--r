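Package: GCtetrads
Title: GC Tetrad Mapping, Tetrad-Abrogated Promoter Design, and
    qPCR/ChIP Quantification for Aureolic-Acid DNA Ligands
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying transcriptional inhibition by minor-groove
    GC-binding antibiotics of the aureolic acid family (olivomycin A,
    mithramycin, chromomycin A3). Scans DNA for degenerate GC tetrad
    binding sites (SGSS/SSCS, S = G or C) on both strands, maps sites and
    transcription-factor ChIP-seq peaks into TSS-relative promoter
    windows, designs tetrad-abrogated promoter mutants (G-to-A
    substitution of the obligate guanine) while preserving protected
    cloning sites, quantifies qPCR time courses by the delta-delta Ct
    method and ChIP-qPCR by dilution-adjusted percent of input, and
    classifies genes into transcriptional sensitivity groups. Includes a
    fully seeded synthetic-data generator with planted ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
biocViews: Transcription, Epigenetics, SequenceMatching, qPCR,
    ChIPSeq, MotifAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
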