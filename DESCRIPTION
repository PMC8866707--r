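Package: ldlbench
Title: LDL Cholesterol Estimator Comparison Workbench
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements and compares low-density-lipoprotein cholesterol
    (LDL-C) estimators computable from the standard lipid panel: the
    Friedewald equation, a Martin-style adjustable-factor method with a
    data-derived strata table, the NIH (Sampson) equation, and a small
    deep-neural-network regressor selected by pyramid candidate
    enumeration, 10-fold cross-validation and tournament selection.
    Ships the corresponding method-comparison statistics (bias with
    one-sample t-test, RMSE, P10/P15/P20 accuracy, clinical category
    concordance, grouped RMSE), pooled-cohort-equation risk scoring with
    vigintile stratification, and a seed-reproducible synthetic cohort
    generator emulating large Korean health check-up populations.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
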