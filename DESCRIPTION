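Package: bedomics
Title: Dose and Electron-Density Radiomics for Late Fibrosis Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for texture-based ("dosiomics") modelling of late
    radiation-induced subcutaneous fibrosis after partial breast
    irradiation. Converts planning CT volumes to relative electron density
    via a scanner calibration curve and physical dose to biologically
    effective dose (BED) under the linear-quadratic model, extracts
    IBSI-style shape, first-order, co-occurrence (GLCM) and run-length
    (GLRLM) features from breast and target-volume regions, rebalances
    outcome classes with an ADASYN implementation, selects features by
    cross-validated deviance of a logistic model, trains support vector
    machine, tree-ensemble and naive-Bayes classifiers, and evaluates them
    with repeated cross-validation, an acceptance gate and a monotonic
    dose-response vetting step. A seeded synthetic phantom cohort generator
    makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
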