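Package: grfnet
Title: Predicting Vertical Ground Reaction Forces from Lower-Limb Joint
    Angles with CNN-xLSTM Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the vertical ground reaction force (vGRF)
    curve of the running stance phase from lower-limb joint-angle time
    series. Implements the full workflow: a seeded synthetic running-gait
    generator (smooth speed-dependent joint-angle curves and a double-peak
    rear-foot-strike vGRF coupled to the angles), the biomechanical
    preprocessing chain (10 N stance detection, zero-phase fourth-order
    Butterworth filtering, time normalization to 101 stance-percent points,
    per-feature min-max scaling, and seven joint/plane input
    factorizations), four sequence-to-curve regressors built from a 1-D CNN
    front end and recurrent stacks (vanilla LSTM, exponential-gated sLSTM,
    matrix-memory mLSTM, and the hybrid xLSTM), and k-fold cross-validated
    evaluation with R-squared, MAPE and rMSE reports, including
    speed-stratified validation. Network forward and backward passes are
    implemented in 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
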