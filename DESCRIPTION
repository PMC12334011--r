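Package: crimedyn
Title: Dynamical-Systems Analysis of Criminal Involvement from Longitudinal Panels
Version: 1.0.0
Authors@R:
    person("Analytic", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a five-state discrete-time compartmental model of
    criminal involvement (inactive, active never-arrested, recently
    arrested, inactive with arrest history, active with arrest history).
    Assigns longitudinal panel records of offending and arrest to model
    states, estimates wave-to-wave transition probabilities by demographic
    subgroup with random-intercept logistic regression, computes the
    long-run equilibrium of the resulting linear system in closed form and
    by stationary-distribution solve, and provides sensitivity, elasticity
    and between-group disparity-decomposition analyses, plus a seeded
    synthetic panel generator for fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
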