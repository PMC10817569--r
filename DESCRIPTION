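Package: ruleboost
Title: Hybrid Rule-Augmented Gradient Boosting for Binary Clinical Risk
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating hybrid clinical risk models
    that combine a gradient-boosted tree classifier on binary predictors
    with a curated knowledge base of conjunctive logical rules that adjust
    the predicted event probability in log-odds space. Includes cohort
    input/output with mode imputation, chi-squared predictor ranking with
    nested best-k sweeps, conjunctive rule mining on binary tables,
    repeated random-split evaluation with F1, AUC, Matthews correlation
    coefficient and expected calibration error, MCC-based model selection,
    vertically averaged ROC curves, paired comparison of models, and a
    synthetic cohort generator with planted rule effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
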