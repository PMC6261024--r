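Package: natremia
Title: Mass-Balance Prediction of Serum Sodium in Critically Ill Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts end-of-epoch serum sodium in intensive-care patients from
    8-hour fluid charts using a mass-conservation balance of water and sodium,
    alongside the classical Adrogue-Madias, Barsoum-Levine, Kurtz-Nguyen and
    electrolyte-free-water-clearance (EFWC) predictors. Includes an inverse
    dosing solver that computes the infusion volume of a chosen solution needed
    to reach a target sodium, method-comparison statistics (Bland-Altman bias
    and 95% limits of agreement, Percentage Similarity with coefficient of
    variation) computed overall and by natremia subgroup, a validated CSV chart
    format, and a seeded synthetic ICU cohort generator for desk-scale testing
    when clinical data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
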