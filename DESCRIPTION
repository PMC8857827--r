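Package: customgrowth
Title: Customized Fetal Growth Standards and Neonatal Nutrition Diagnostics
Version: 0.1.0
Authors@R:
    person("Puerto Real", "Perinatal Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies fetal and newborn size against a customized
    (Gardosi-type proportionality) growth standard and against table-based
    population standards, computes neonatal nutritional status from sex- and
    gestational-age-specific body-mass-index and ponderal-index references,
    and compares the diagnostic performance of competing size classifications
    for predicting neonatal undernutrition (sensitivity, specificity,
    predictive values, likelihood ratios, diagnostic odds ratio, Youden
    index, relative risks with Katz intervals, Altman-Bland and McNemar
    comparisons). Includes a synthetic cohort generator emulating
    hypertensive-disorder-of-pregnancy populations so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
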