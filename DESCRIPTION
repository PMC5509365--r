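Package: divpred
Title: Divisive Predictive Coding for Sensory Inference under Signal-Dependent Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative models of early sensory processing when input noise
    scales with the signal. Implements maximum-likelihood estimation of
    nonnegative stimulus features under a linear-Poisson generative model via
    fractional-prediction-error (divisive) dynamics, the subtractive
    Gaussian-noise counterpart and its closed form, a two-population
    excitatory/inhibitory rate-network realization with divisive inhibition
    on the leak, a linear-nonlinear (LN) baseline, and the measurement
    machinery used to characterize such models: reverse-correlation
    receptive fields, contextual tuning curves, linear population readouts,
    gain-control and temporal-dynamics protocols, plus preset experiments
    that regenerate the characteristic phenomena (contextual receptive-field
    reshaping, tuning-curve shifts, invariant readout, divisive
    normalization, contrast-dependent latencies, traveling waves).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
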