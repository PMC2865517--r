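Package: neurokf
Title: Unscented Kalman Filter Data Assimilation for Conductance-Based
    Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint state and parameter estimation for biophysical neuron
    models from a single noisy membrane-potential recording.  Implements a
    Hodgkin-Huxley-type pyramidal cell / OLM interneuron model with a
    dynamic ion microenvironment (extracellular potassium, Na-K pump,
    glial buffering, bath and lateral diffusion), fuses it with voltage
    observations through an unscented Kalman filter with equal-weight
    sigma points, and provides twin-experiment drivers that validate
    reconstruction of gating variables, ion concentrations,
    microenvironment parameters and unobserved coupled cells, including
    seizure-like episodes.  The filter inner loop and model right-hand
    sides are implemented in C++ for speed, with reference R
    implementations retained for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
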