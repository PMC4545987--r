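Package: raschpro
Title: Rasch Measurement Evaluation for Patient-Reported Outcome Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calibration and psychometric evaluation of mixed
    dichotomous/polytomous patient-reported outcome questionnaires under the
    Rasch family of models (rating scale and partial credit), estimated by
    joint maximum likelihood. Provides residual-based item and person fit
    statistics, person reliability and separation, dimensionality screening by
    principal component analysis of standardized residuals, local-independence
    checks, item-person targeting, threshold range and coverage, gap detection,
    ceiling and floor effects, text Wright maps, and differential item
    functioning by anchored group calibrations with a logit-contrast rule.
    Includes a synthetic response generator emulating the structure of the
    St. George's Respiratory Questionnaire so every pipeline stage can be
    verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
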