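Package: hfgap
Title: Estimating the Hidden Burden of Heart Failure in Administrative Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based phenotyping of potential heart-failure (HF) cases and
    HF-related deaths in ambulatory claims and mortality records, a
    deterministic sensitivity analysis of the resulting underestimation of the
    diagnosed HF burden, and a leakage-guarded early-prediction workflow:
    washout-windowed feature construction, balanced and low-prevalence cohort
    assembly, gradient-boosting and penalised-logistic risk models with
    two-stage hyperparameter search, and discrimination plus calibration
    assessment (Brier, ECE, MCE, Hosmer-Lemeshow, calibration slope and
    intercept). Ships a synthetic claims generator with known latent disease
    status so every stage is testable without access to the source registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    xgboost,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    arrow,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
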