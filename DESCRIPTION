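Package: motorlimits
Title: Efficiency Limits of Non-Processive Molecular Motor Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechano-chemical modelling of non-processive motors of the
    myosin family. Defines kinetic cycles with strain-dependent transition
    rates obeying generalized detailed balance, solves the stationary
    master equations for the bound-state strain densities of an ensemble
    sliding at constant velocity, and computes force-velocity relations,
    ATPase flux, per-transition entropy production and thermodynamic
    efficiency. Includes constrained multi-start optimizers that determine
    theoretical efficiency limits under caps on stiffness and nucleotide
    binding rates (including functional optimization of anharmonic elastic
    potentials), a Gillespie simulator of finite motor ensembles pulling a
    rigid filament against constant load, and closed-form soft-spring
    analytics used as independent cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    lhs,
    Matrix
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
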