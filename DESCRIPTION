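Package: phqpairs
Title: Two-Item Depression Screening Instruments from PHQ-9 Item Pairings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating ultrabrief (two-item) depression
    prescreening instruments from the nine PHQ-9 items. Fits a regularized
    logistic classifier to every one of the 36 item pairings, analyses the
    discrete 16-pattern probability lattice each model induces, selects decision
    thresholds by maximum cross-validated Youden index, ranks pairings by
    cross-validated AUC, and evaluates frozen instruments against conventional
    sum-score cutoffs (such as the PHQ-2 cutoffs of 2 and 3) on held-out data.
    Includes a Gaussian-copula simulator for correlated skewed ordinal
    questionnaire items with tunable screen-positive prevalence, so the whole
    pipeline can be exercised and tested without access to survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
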