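Package: asterdyn
Title: Repulsive-Potential Models and Track Analytics for Microtubule
    Aster Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for the positioning of microtubule
    asters in quasi-two-dimensional cytoplasmic droplets (embryo explants).
    Implements an overdamped agent model in which each aster generates a
    short-range, slip-inhibited exponential repulsion against the droplet
    boundary (via a mirror charge) and against other asters, with 1D and 2D
    Euler simulation engines, analytic steady states, and stochastic
    ensembles. Companion analytics cover trajectory kinematics (separation
    series, steady-state geometry, perturbation-response and ablation
    statistics), yolk-granule tracking (anomalous-diffusion MSD exponents,
    exclusion-zone tests, aster-frame velocity fields), microtubule
    intensity profiles (radial binning, mono-exponential decay fits,
    kymographs, separation-velocity model fits), and seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
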