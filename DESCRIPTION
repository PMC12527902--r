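Package: dceweights
Title: Discrete Choice Experiment Design, Estimation and MCDA Criterion
    Weights for Orphan-Drug Value Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building multi-criteria decision analysis (MCDA)
    criterion weights from stated-preference data, motivated by orphan-drug
    reimbursement decisions. Covers the full workflow of a discrete choice
    experiment (DCE): a packaged seven-attribute value schema for orphan
    drugs, D-efficient paired choice-set design by coordinate exchange with
    blocking and a repeated consistency task, simulation of respondent
    panels from a mixed-logit data-generating process, questionnaire
    validity screening, conditional and panel mixed logit estimation by
    maximum simulated likelihood with Halton draws, and conversion of
    part-worth utilities into relative-importance weights,
    willingness-to-pay, and SMART (Simple Multi-Attribute Rating Technique)
    direct weights, with method-concordance diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
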