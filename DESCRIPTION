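Package: micoxpen
Title: Penalised Cox Prognostic Models with Multiply Imputed Training Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Develops and validates prognostic models for overall survival when
    the training dataset has missing covariate data. Implements multiple
    imputation by chained equations (predictive mean matching for continuous
    covariates, proportional-odds models for ordinal covariates),
    LASSO-penalised Cox regression with a single cross-validated penalty shared
    across imputations, Rubin's-rules pooling of coefficients and bootstrap
    standard errors, model assessment by Kaplan-Meier calibration, the
    prognostic-separation D-statistic (Bloom rankits) and Uno's C, bootstrap
    internal validation with nested re-imputation and optimism correction,
    complete-case and imputed external validation, and tertile risk-group
    derivation. Includes a seeded generator of myeloma-trial-like synthetic
    datasets with known truth for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    glmnet,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
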