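Package: pfilasso
Title: Stability-Tuned Lasso Models of the Platinum-Free Interval from
    Ascites Protein Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts the platinum-free interval (PFI, days to recurrence
    after platinum chemotherapy) of high-grade serous ovarian cancer
    patients from multiplexed bead-based immunoassay panels of ascites
    proteins.  Provides censored-immunoassay preprocessing (75% detection
    filter, limit-based imputation, log10 and Yeo-Johnson normalization),
    L1-penalized (Lasso) regression with leave-one-out and nested
    leave-one-out cross-validation over a log-spaced penalty grid,
    error-budget penalty relaxation, model-stability diagnostics
    (fold-wise coefficient percent CV and inclusion counts), cross-cohort
    prediction, cohort descriptive statistics, and a synthetic-cohort
    generator emulating the statistical structure of such studies so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
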