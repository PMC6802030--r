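Package: fgmconflict
Title: Evolutionary Conflict over Joint Phenotypes in Fisher's Geometric Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one-trait adaptive walks in Fisher's geometric model
    extended to two-party evolutionary conflict over a joint phenotype, such
    as the probability that a pathogen infects a host. Supports the standard
    single-optimum model, a two-party conflict model in which each party pulls
    the shared trait toward its own optimum, and a magnitude-matched
    moving-optimum control that mimics abiotic environmental change. Walks
    proceed by successive fixation under strong-selection/weak-mutation
    dynamics with Kimura fixation probabilities for finite or infinite
    populations. Provides equilibrium summary statistics (distance to optimum,
    fitness, fixation fraction and size, lag load), fitness-power analysis of
    asymmetric parties, replicate aggregation, experiment grids with
    deterministic seeding, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
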