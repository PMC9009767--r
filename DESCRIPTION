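Package: gainsweep
Title: Global Gain Modulation of Hierarchical Visual Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a single global gain parameter, a
    computational proxy for cortical arousal, reshapes perceptual
    decision-making in small residual convolutional networks. Provides a
    synthetic image generator with parametric perceptual difficulty
    (real-versus-average discrimination and multi-category recognition),
    a trainable residual backbone whose activation functions are all
    scaled by one gain scalar, per-condition head fine-tuning at neutral
    gain, performance-gain sweeps with signal detection measures (d-prime,
    criterion) and ROC AUC, block-wise linear decoding probes, and a
    spatial-scrambling perturbation with importance-curve calibration and
    progressive disruption experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    png,
    rlang,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
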