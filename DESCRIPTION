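Package: predcoding
Title: Predictive Coding and Free-Energy Neural Circuit Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for the free-energy / predictive-coding account
    of perception and learning in simple neural circuits. Provides exact
    grid-based Bayesian posteriors for scalar Gaussian generative models,
    gradient-ascent and prediction-error-node inference dynamics, Hebbian
    learning rules for means, variances and observation mappings, the
    multivariate and hierarchical generalizations of the circuit, and an
    extension with inhibitory interneurons in which variances and covariances
    are learned with strictly local Hebbian plasticity, including linear
    stability analysis of the error-unit dynamics. Includes a fixed-step Euler
    integrator, seeded synthetic trial generators, a finite-difference
    gradient checker, and runners reproducing the standard worked exercises.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
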