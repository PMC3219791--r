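Package: droughtseq
Title: Differential Expression and Enrichment Analysis for Multi-Condition
    Osmotic-Stress RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for bulk RNA-seq studies of osmotic
    stress and hormone response in cereals. Implements lane-level count QC
    and quantile normalization, a common-dispersion negative-binomial exact
    test with a three-part differential-expression filter (adjusted p,
    log2 fold change, median sequencing depth), Z-score and exact
    hypergeometric gene-set enrichment, length-bias-corrected GO enrichment
    via the Wallenius noncentral hypergeometric distribution, metabolic
    pathway reaction coverage and cross-talk network construction, IUPAC
    degenerate cis-element scanning of promoter regions, and a cross-species
    decision tree for triaging drought-responsive genes of unknown function.
    A synthetic-data generator with full ground truth emulates a
    two-tissue, two-contrast, three-replicate experimental design so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
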