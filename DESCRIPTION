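Package: refh
Title: Recurrent Exponential-Family Harmoniums for Neural Filtering of
    Dynamical State
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how a recurrent exponential-family harmonium
    (a temporal restricted Boltzmann machine with Poisson visible units and a
    one-step-delayed copy of its own hidden layer among its inputs) learns,
    without supervision, to track the state of a linear dynamical system from
    probabilistic population codes.  Includes simulators for damped
    harmonic-oscillator joint dynamics with optional control (torque) input,
    Gaussian-tuned Poisson population encoders and center-of-mass decoders,
    contrastive-divergence training and deterministic filtering for the
    harmonium, a Poisson-population-code variant of the Kalman filter with
    RTS smoothing and expectation-maximization parameter learning as
    benchmarks, error-statistics and model-selection protocols, and
    receptive-field / lagged mutual-information tuning analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
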