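Package: cgmforecast
Title: Blood Glucose Forecasting from CGM Data with Kalman Smoothing and
    Stacked LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for short-horizon blood-glucose forecasting in type-1
    diabetes from continuous glucose monitoring (CGM) streams. Reads
    OhioT1DM-style per-patient XML event files and an equivalent CSV dialect
    onto a uniform 5-minute grid, corrects CGM sensor faults with a Kalman
    filter and Rauch-Tung-Striebel smoother, crafts physiological input
    channels (effective carbohydrates, effective bolus insulin, weighted step
    counts), and trains a stacked-LSTM probabilistic forecaster with a
    Gaussian negative log-likelihood loss to predict glucose 30 or 60 minutes
    ahead. Includes a seeded type-1-diabetes patient simulator with injected
    sensor faults (dropouts, spikes, pressure-induced attenuation) so the full
    pipeline is testable without access-restricted clinical data, plus RMSE
    evaluation against fingerstick and reference glucose and a persistence
    baseline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
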