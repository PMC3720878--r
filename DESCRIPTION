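Package: synsurr
Title: Surrogate Modeling of AMPA Receptor Activation in Stochastic Synapse Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building machine-learning surrogates of stochastic
    synapse simulations. Generates corpora of model synapses with variable
    geometry, receptor and transporter densities, simulates the percentage of
    open AMPA receptors after glutamate release with a compartmental binomial
    tau-leap engine, and learns a receptor activation function through a
    five-stage pipeline: peak-oversampled curve sampling, configuration-level
    fold creation, M5-style model-tree regression, cross-validated RMSE/R^2
    evaluation, and nonlinear least-squares fitting of rational or Fourier
    curve families to the predicted points. Includes a 65-candidate
    curve-family selection study, coefficient linear models, and parameter
    sensitivity correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
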