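Package: fibroscores
Title: Noninvasive Liver Fibrosis Scores and Their Diagnostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for eight composite blood-based liver fibrosis
    scores (FIB-4, NFS, APRI, BARD, HFS, ADAPT, FIBC3, MACK-3) together with
    the diagnostic-accuracy toolkit needed to evaluate them in nonalcoholic
    fatty liver disease cohorts: sensitivity, specificity and predictive
    values with exact confidence intervals, likelihood ratios and number
    needed to diagnose, dual-cutoff classification with indeterminate zones
    and age-adjusted thresholds, ROC curves with DeLong inference, the
    Obuchowski measure for ordinal fibrosis stage, paired comparisons of
    rates and predictive values, BMI-stratified derivation and validation
    of rule-out and rule-in cutoffs, sequential two-test triage algorithms,
    and a synthetic patient-cohort generator with stage-dependent biomarker
    distributions for end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    broom,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
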