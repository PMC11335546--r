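Package: adastack
Title: Adaptive Stacking Ensembles for Binary Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Constructs two-layer stacked-generalization ensembles for binary
    tabular classification with adaptive base-classifier selection: candidate
    classifiers are screened by cross-validated F1 against a mean-F1 threshold,
    then pruned for redundancy with the pairwise Q-statistic of classifier
    diversity, and out-of-fold predictions feed a meta-learner chosen by
    traversal of the surviving families. Includes gradient-boosting feature
    filtering via Shapley-value attributions, a registry of ten classifier
    families behind a uniform train/predict contract, confusion-matrix and
    rank-based AUC metrics, a synthetic generator emulating the BRFSS
    diabetes-health-indicators schema, and an end-to-end pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    nnet,
    randomForest,
    rpart,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
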