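Package: tierdyn
Title: Dynamics of Patient Visits Across China's Three-Tier Hospital System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a three-compartment logistic model of monthly patient
    visit counts at first-, second- and third-level hospitals, with
    leapfrog-transfer terms (patients skipping to higher tiers) and churn.
    Provides the vector field and its closed-form equilibria, local stability
    classification from the Jacobian eigenvalues, trajectory simulation and
    parameter-sensitivity sweeps, bounded nonlinear least-squares estimation
    of the twelve model parameters from observed monthly series, and a
    synthetic-data generator for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
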