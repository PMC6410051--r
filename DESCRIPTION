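Package: meriptools
Title: Windowed m6A Peak Calling and Epitranscriptome Integration for
    MeRIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing m6A MeRIP/RIP-seq experiments together with
    matched RNA-seq: a sliding-window peak caller on transcript coordinates
    using a gene-median-normalised log2 enrichment score with one-sided
    Fisher testing and Benjamini-Hochberg correction, metagene profiling of
    peaks over rescaled 5'UTR/CDS/3'UTR segments, integration of differential
    peaks with differential expression into direct and indirect
    methyltransferase target classes, an RNA-editing detection filter
    cascade, post-filters for rMATS differential-splicing tables, RBP/m6A
    cooperation statistics, and a seed-reproducible synthetic-data generator
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    data.table
Config/testthat/edition: 3
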