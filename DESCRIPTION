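Package: fetonet
Title: Multi-Tissue Two-Condition Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting gene co-expression networks between two
    experimental conditions across multiple tissues, as used in fetal
    programming studies of maternal nutrient restriction. Implements the Tau
    tissue-specificity index, regulatory impact factors (RIF1/RIF2) for
    transcription factor prioritisation, PCIT (partial correlation and
    information theory) network inference with the |r| > 0.9 edge rule,
    differential co-expression classification via the Fisher z test with the
    sign/significance correlation classes, and differential connectivity (DK)
    analysis of condition-specific networks. A negative-binomial synthetic
    data generator with planted tissue-specific genes, differentially
    expressed genes and condition-rewired regulator modules makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
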