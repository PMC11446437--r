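Package: cervshift
Title: Generalizability and Repeatability Evaluation of Ordinal Cervical-Image Classifiers Under Device and Geography Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how a three-class (normal / indeterminate /
    precancer+) cervical-image triage classifier behaves when it is moved to
    data collected with a new image-capture device or in a new geography.
    Provides a synthetic multi-site cohort simulator with woman-level repeat
    images and separately tunable device and geography effects, a rule engine
    that assigns ordinal ground truth from histology, high-risk HPV status and
    expert review, a seeded multinomial-logistic stand-in classifier with
    class-balanced retraining, classification metrics (one-vs-rest AUROC with
    woman-clustered bootstrap confidence intervals, confusion matrices,
    extreme and total misclassification rates), test-retest repeatability
    metrics (Bland-Altman 95% limits of agreement over per-woman maximum
    score differences, extreme disagreement), and orchestration of two
    experiment suites: a three-run device-versus-geography heterogeneity
    comparison and a ratio-controlled incremental-retraining saturation study
    with a catastrophic-forgetting check.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    nnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
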