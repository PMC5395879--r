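Package: airwaycollapse
Title: Nonlinear Finite-Element Simulation of Tracheal Collapse in
    Tracheomalacia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Ogden hyperelastic constitutive models to tracheal
    tissue stress-strain data, builds parameterized idealized pediatric
    trachea meshes with cartilage rings, fibrous gaps, trachealis muscle
    and mucosal lining, and simulates exhalation-driven large-deformation
    airway collapse with follower pressure loading, frictionless
    self-contact and arc-length continuation through snap-through
    instability. Collapse severity is quantified by lumen area-ratio
    curves, an instability-onset criterion based on linear extrapolation
    of the force versus area-ratio path, and wall-strain summaries across
    diameter by malacic-length by severity sweeps.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
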