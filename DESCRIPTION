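Package: spheroseq
Title: Transcriptome Regulation Analysis for Early-Stage Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-condition (monolayer versus
    multicellular tumor spheroid) bulk RNA-seq transcriptomes. Applies a
    read-count and relative-expression detection filter, classifies each
    transcript's regulation as up, down, de novo, switched off, unchanged or
    filtered using a signed (negative-reciprocal) fold-change convention, maps
    regulated long non-coding RNAs to their nearest protein-coding neighbors
    and classifies concordant or discordant co-regulation, detects
    window-chained chromosomal clusters of dysregulated features, computes
    per-chromosome distribution statistics (length and gene-density Pearson
    correlations, strand-bias chi-square), and evaluates oxygraph respirometry
    quantities (OxPhos flux, uncoupling ratio) and spheroid geometric-mean
    diameters. A seeded negative-binomial simulator with planted effects
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
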