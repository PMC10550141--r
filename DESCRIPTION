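Package: refbias
Title: Apparent Accuracy Metrics and Prevalence Under Imperfect Reference Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form forward models for how an imperfect reference
    standard distorts binary-classification accuracy metrics (recall,
    precision, specificity, NPV, Youden's J, F1, the Matthews correlation
    coefficient and likelihood ratios) and the apparent prevalence, under
    conditionally independent and maximally correlated reference errors.
    Includes the full confusion-matrix metric suite, prevalence sweeps over
    standard scenario sets, a case-level synthetic-data generator whose
    expected cross-tabulation equals the closed forms (a Monte-Carlo
    oracle), the algebraic bias-correction inverting the independent-error
    model (Rogan-Gladen style), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
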