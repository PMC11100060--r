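Package: SwallowQuant
Title: Detection and Quantification of Ingestive Activity from Neck sEMG and
    Wrist Inertial Angles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for monitoring eating and drinking from a
    single-channel surface electromyography (sEMG) recording over the
    sternocleidomastoid muscle fused with wrist-mounted inertial (tilt angle)
    streams. Includes a protocol-faithful synthetic cohort generator with
    ground-truth event labels, interference-based stream synchronization,
    wrist-angle activity demarcation and sEMG event segmentation, a registry
    of forty time-frequency sEMG features, cascaded classification and
    regression models for solid bolus type and weight, water sip volume
    regression, Levenberg-Marquardt and Bayesian-regularized feed-forward
    network training, a one-dimensional convolutional sip-volume classifier,
    and an among-subject / cross-subject fivefold evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    rpart,
    ranger,
    e1071,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
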