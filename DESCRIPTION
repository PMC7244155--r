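Package: ebitrack
Title: Extended Bayesian Inference for Tracking Non-Stationary Gaussian Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Online estimation of the mean and variance of a univariate,
    piecewise-stationary Gaussian data stream by extended Bayesian inference
    (EBI): Bayesian confidence updating with a forgetting rate, plus
    inverse-Bayesian learning in which the model of the maximum-confidence
    hypothesis is modified by closed-form inversion of the normal density
    (for the mean) and of the gamma density via the Lambert W function (for
    the variance).  Includes the sequential discounting EM (SDEM) and
    exponential moving average (EMA) baselines, a non-stationary task
    generator, and an evaluation harness computing followability and
    accuracy root-mean-square errors with discount-rate and (alpha, m)
    parameter sweeps.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
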