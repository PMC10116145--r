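Package: c3b
Title: Scoring, Regression-Based Norms, and Screening Diagnostics for a
    Computerized Cognitive Battery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the computational core of a two-test computerized
    cognitive screening battery: stimulus generation and scoring for a
    visual memory test (7 symbols on a 4x6 board, 5 learning trials with a
    discontinue rule) and a symbol-digit processing speed test (120-second
    response window); demographically adjusted z-scores from published
    regression-based norms with quadratic and knotted age terms; refitting
    of the normative regressions on new cohorts; screening classification
    with confusion-matrix diagnostics, ROC/AUC and Youden-optimal cutoffs;
    test-retest reliability (paired t, paired Cohen's d, intraclass
    correlation); and seeded synthetic cohort generators that emulate the
    normative stratification, MCI case-control samples and retest pairs so
    the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
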