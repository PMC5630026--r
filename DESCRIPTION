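Package: creevo
Title: Cross-Species Analysis of Cis-Regulatory Element Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparative epigenomics of
    cis-regulatory elements (CREs) across a six-species primate phylogeny.
    Maps human CRE intervals to orthologous regions through multiple sequence
    alignment blocks, tests differential histone modification with a
    negative-binomial GLM using an IP-by-input interaction design and Wald
    statistics, classifies CREs as conserved or lineage-specific from a
    human-centric battery of phylogenetic comparisons, estimates pairwise
    sequence divergence with outlier removal, measures transposable-element
    family enrichment by permutation, and links regulatory divergence to
    expression divergence with stratified association statistics. Ships a
    synthetic-data generator that emulates the full study design with known
    ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
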