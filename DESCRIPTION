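Package: lncscreen
Title: Long Noncoding RNA Discovery, Knockout Screening and ceRNA Candidate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream computational workflow of
    bulk RNA-seq lncRNA studies: calling novel long noncoding RNA candidates from
    assembled transcript annotations (length/exon filters and a four-predictor
    coding-potential consensus), classifying them into the four positional classes
    (lincRNA, intronic, antisense, sense), negative-binomial differential expression
    at study thresholds with Benjamini-Hochberg correction, a knockout-versus-wildtype
    double-ratio screen for regulated genes with hierarchical expression-profile
    clustering, and transparent miRNA seed-site scanning for competing endogenous RNA
    (miRNA sponge) candidate discovery, including binding-site deletion mutants for
    reporter designs. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
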