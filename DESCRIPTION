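Package: nptpredict
Title: Predicting Nasal Provocation Test Outcome from IgE-Specific
    Activity and Seasonal Symptom Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnostic-accuracy analysis of grass-pollen
    nasal provocation test (NPT) outcome in poly-sensitized seasonal
    allergic rhinitis. Computes molecular IgE-specific activity indices
    (allergen-specific IgE as a percentage of total IgE), derives
    pollen-season windows and high-pollen-day masks from daily grain
    counts, summarizes symptom e-diaries (RTSS, CSMS, VAS) as maxima and
    coefficients of variation over high-pollen days, and evaluates
    predictors by empirical ROC curves with Youden-optimal cutoffs,
    confusion-matrix metrics, exact and corrected two-group tests, and
    binary logistic regression with Wald inference, Nagelkerke R-squared
    and Box-Tidwell linearity checks. Includes a synthetic cohort,
    pollen and e-diary generator so the full pipeline is testable
    without patient-level data, and an evaluator for combined
    "activity or VAS" diagnostic rules.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
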