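Package: lysolatch
Title: Stochastic Simulation of the Lambda Phage Lysis-Lysogeny Decision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic simulation of the early lambda phage gene
    circuit (CI, Cro, CII) in single infected bacteria, with tools for
    studying how the multiplicity of infection shapes the lysis-lysogeny
    decision at fixed viral concentration. Provides a direct-method
    Gillespie simulator with scheduled events (phage replication, delayed
    infection) and growth coupling (dilution, volume growth, transcription
    scaling), the matching deterministic mean-field integrator,
    threshold-based decision statistics with a Gaussian analytic
    approximation and a phenomenological reference model, a one-dimensional
    compartmentalized reaction-diffusion variant for phage placement
    effects, figure-level experiment drivers, and a synthetic time-lapse
    cohort generator with elongation-rate estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
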