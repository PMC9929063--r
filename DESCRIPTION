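Package: obscreen
Title: Derivation and Application of Stepwise Obstetric Social-Support Screening Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies points-based stepwise screening tools that flag
    pregnant women likely to need coordinated social support (public-health-center
    referral) from short structured interview sheets administered at obstetric
    visits. Implements the full derivation pipeline: risk-coding of questionnaire
    answers into binary indicators, crude and adjusted regression fits
    (standardized linear coefficients for item scoring, maximum-likelihood
    logistic odds ratios with Wald intervals), sign-reversal and sparsity item
    exclusion, coefficient-times-100 scoring, ROC/Youden cutoff selection,
    prevalence- and rank-correlation-based construction of the second and third
    screening stages, and acceptance or rejection of a candidate tool by AUC.
    Ships reference first-visit and second-trimester tools, a synthetic-cohort
    generator reproducing the assumed statistical structure of such cohorts, a
    funnel reporter for stage-by-stage screening yield, and an analysis of
    associations between interview items and an Edinburgh Postnatal Depression
    Scale total of 9 or more.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
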