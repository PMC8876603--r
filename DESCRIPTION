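Package: gridock
Title: Grid-Potential Docking and Virtual-Screening Triage for Serine
    Protease Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structure-based virtual-screening engine built around
    grid-potential protein-ligand docking. Precomputes Coulomb, Lennard-Jones
    and generalized-Born desolvation potentials on a docking cube, searches
    ligand poses (rigid placement plus rotatable torsions) with a genetic
    algorithm, assesses reliability by clustering the best poses of independent
    runs, rescoring shortlisted poses with a thermodynamic-cycle binding
    enthalpy after local optimization, detects hydrogen bonds and pi-stacking,
    and applies a screening funnel (score cutoff, cluster population, pocket
    occupancy, binding-enthalpy ranking) together with ADME and exact-mass
    descriptors. Ships a synthetic-fixture generator with planted binding
    minima and brute-force search oracles so every stage is testable without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
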