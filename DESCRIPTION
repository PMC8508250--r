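Package: edrisk
Title: Preoperative Radiomic Risk Modeling of Early Distant Recurrence
    After Pancreatic Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for building and evaluating a preoperative
    prognostic index for early distant recurrence (< 12 months) after upfront
    pancreaticoduodenectomy. Provides synthetic CT tumor phantoms and cohort
    simulators, IBSI-style radiomic feature extraction (morphology, intensity
    statistics, grey-level texture matrices), a three-stage feature-selection
    cascade (delineation-robustness ICC screen, Spearman redundancy filter,
    bootstrap-frequency ranking), a compact backward logistic model with a
    Youden-optimal risk cutoff, and Kaplan-Meier / Cox evaluation of the
    resulting risk groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
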