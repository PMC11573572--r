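Package: maomtools
Title: Structural Analysis of Mineral-Associated Organic Matter Configurations
Version: 0.1.0
Authors@R:
    person("MAOM", "Tools Developers", email = "maomtools@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular configurations of soil
    organic matter (SOM) at mineral surfaces. Builds molecule-level contact
    graphs under periodic boundary conditions, finds SOM aggregates and the
    largest cluster, classifies per-molecule sorption modes (direct contact,
    cation bridging, SOM bridging, interfacial, evaporated, free), quantifies
    per-layer mineral surface coverage by water, ions and SOM with periodic
    two-dimensional Voronoi tessellation, computes polar and apolar
    solvent-accessible surface areas (Shrake-Rupley), assembles per-species
    chemical descriptor tables (mass, double bond equivalents, van Krevelen
    ratios) and correlates them with clustering and bridging probabilities
    using Spearman rank statistics. A synthetic-scene generator plants
    configurations with known ground-truth labels so that every stage of the
    pipeline is testable at desk scale without trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
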