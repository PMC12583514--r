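Package: urchintherm
Title: Bayesian Analysis of Thermal Suppression of Sea Urchin Gametogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative simulation and Bayesian analysis of mesocosm
    experiments on thermal suppression of gametogenesis in the purple sea
    urchin (Strongylocentrotus purpuratus). Builds constant and simulated
    El Nino / La Nina thermal schedules, generates per-animal datasets with
    the split-plot and replicated-mesocosm structure of the experiments,
    fits a Bayesian multinomial model of gametogenic stage with a
    Gaussian-process temperature smoother and a hierarchical Gamma model of
    gonad mass (Hamiltonian Monte Carlo with analytic gradients), estimates
    marginal likelihoods by bridge sampling for Bayes-factor model
    comparison with simulation-based calibration, and summarizes posteriors
    with highest-posterior-density intervals and derived contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
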