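Package: cmcdcm
Title: Dynamic Causal Modeling of Basal Ganglia Modulatory Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation and Bayesian inversion of five-region
    dynamic causal models (DCM) built on the Common Model of Cognition, for
    resting-state BOLD fMRI. Implements the bilinear neural state equation
    with second-order (modulatory) basal ganglia connections, a
    balloon-Windkessel hemodynamic observation model, low-frequency boxcar
    drivers for deterministic resting-state DCM, variational-Laplace model
    inversion with a free-energy approximation to the log model evidence,
    fixed-effects Bayesian model selection via the log group Bayes factor,
    Bayesian parameter averaging with directional group tests, and an
    ROI-level regressor-quality check. Synthetic cohorts with
    Parkinson's-disease-like and control-like parameter regimes support
    end-to-end parameter-recovery and model-selection experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
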