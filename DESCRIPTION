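Package: ironpredict
Title: Questionnaire-Based Prediction Models for Serum Iron Biomarkers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and internal validation of questionnaire-based
    prediction models for three serum iron-status biomarkers (serum iron,
    ferritin, transferrin saturation) in a cohort of women stratified by
    menopause status. Provides a synthetic cohort generator calibrated to
    published marginal distributions, regression coefficients and
    correlation structure; multiple imputation by chained equations with
    predictive-mean matching; Rubin's-rules pooling; pooled backward
    elimination and a stacked, weighted lasso for variable selection under
    multiple imputation; and Harrell's bootstrap optimism correction with
    calibration slopes, per imputation and pooled.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    glmnet,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
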