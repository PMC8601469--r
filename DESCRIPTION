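Package: dictywave
Title: Stochastic Excitable-Medium Simulation of Mixed Dictyostelium
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates cyclic-AMP wave propagation during the aggregation
    phase of Dictyostelium discoideum as a stochastic excitable medium on a
    square lattice. Cells are randomly placed at a chosen density and split
    into proactive (signal-amplifying, cubic Barkley kinetics) and reactive
    (non-amplifying, linear kinetics) types; the recovery variable of every
    cell is driven by Ornstein-Uhlenbeck colored noise. The package provides
    a compiled semi-implicit integrator, generators for random mixed
    populations, the full statistical analysis of the resulting fields
    (spatial mean and fluctuation width, nearest-neighbor synchrony index,
    exponential-growth/plateau crossover time, kymographs), a
    phase-singularity heuristic for labelling circular versus spiral wave
    regimes, and a survey driver over population composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
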