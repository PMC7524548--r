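Package: barrelmap
Title: Self-Organization of Whisker Barrel Maps by Guided Reaction-Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the emergence of the rodent whisker barrel map in
    primary somatosensory cortex as a self-organizing process. Thalamocortical
    projections carry axon branching and connection densities over a hexagonal
    lattice discretization of the cortical sheet; branching diffuses, is
    advected by molecular guidance gradients with projection-specific
    interaction strengths, and is repelled by the branches of competing
    projections (a cross-diffusion competition term). The coupled dynamics are
    integrated with a fourth-order Runge-Kutta scheme under no-flux boundary
    conditions. The package provides the lattice operators, guidance-field
    construction, pattern-quality metrics (Voronoi conformance, pattern
    difference, connection selectivity), synthetic input generators, and
    scripted in-silico experiments: parameter sweeps, sensitivity analyses,
    mirror-duplication of the map, and whisker-trimming perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
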