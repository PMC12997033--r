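Package: uqeval
Title: Evaluation and Recalibration of Predictive Uncertainty
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing and improving the reliability of
    probabilistic predictions from clinical machine-learning models.
    Aggregates ensemble and Monte-Carlo-dropout member outputs into single
    predictive distributions, converts between Gaussian, quantile and
    interval output types, applies post-hoc recalibration (temperature and
    variance scaling, isotonic regression, split conformal prediction,
    conformalized quantile regression, Venn-ABERS), and computes a
    multi-scale suite of calibration metrics for binary classification
    (ECE, ACE, smECE, UCE, VCE, NLL, AUC) and regression (ENCE, CRPS, PICP,
    CCE, Gaussian NLL, MAE/MASE), with per-group adaptive evaluation,
    paired bootstrap model comparison, and synthetic prediction-set
    generators with known calibration defects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
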