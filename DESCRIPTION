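Package: methnet
Title: Integrative Brain Methylome and Transcriptome Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for case-control integration of
    DNA methylation (Illumina 450K-style beta matrices) and RNA-seq
    expression data. Implements probe-level quality filtering and beta/M
    conversion, per-CpG differential methylation with empirical-Bayes
    moderation, kernel-smoothed differentially methylated region (DMR)
    calling with FDR and delta-beta thresholds, detection of
    protein-interaction modules enriched for differential methylation
    with permutation significance, Horvath-style epigenetic clock
    application with age-acceleration statistics, CPM-based expression
    filtering and a simple differential-expression model, cross-source
    PPI network integration with seven centrality metrics and
    95th-percentile hub selection, DMR-anchored transcription-factor
    regulatory network construction, cohort-table statistics, and a
    synthetic-data generator with planted truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
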