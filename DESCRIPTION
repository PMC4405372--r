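Package: diapauseTx
Title: Hybrid Reference-Guided Transcriptome Re-Assembly and
    Diapause-Induction Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a hybrid
    transcriptome analysis workflow for a non-model mosquito: paired-end
    read cleaning (vector/adapter screening, quality trimming, digital
    normalization by median k-mer coverage), within-stage contig
    de-duplication, protein- and genome-reference-guided contig
    re-assembly and annotation (chimera detection, percentile retention,
    UTR classification), expectation-maximization unigene quantification,
    TMM-normalized negative-binomial differential expression under a 2x2
    photoperiod-by-blood-meal factorial design, and length-bias-corrected
    pathway enrichment. A seeded synthetic-data generator emulates the
    multi-stage contig sets and the 16-library factorial sequencing
    experiment so that every stage is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
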