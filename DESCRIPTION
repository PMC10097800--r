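Package: hemopso
Title: Stress-Based Hemolysis Model Optimization with Multi-Objective
    Particle Swarm Search
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Solver-decoupled evaluation and optimization of stress-based
    power-law hemolysis models. Computes the modified index of hemolysis
    (MIH) as a discrete volume integral over exported finite-volume stress
    fields, scores candidate power-law constant sets (C, alpha, beta)
    against experimental hemolysis measurements with uncertainty dead-band
    error and modified-correlation objectives, searches the constant space
    with a multi-objective particle swarm optimizer (constriction-factor
    updates, Pareto repository with adaptive hypercube grid), and extracts
    the principal-component line along which near-optimal constant sets
    align. Includes analytic and synthetic stress-field generators so the
    whole pipeline is testable without a flow solver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
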