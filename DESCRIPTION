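Package: syntromix
Title: Individual-Based Simulation of a Food-for-Detoxification Biofilm Mutualism
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the growth of a two-species surface-attached microbial
    community in which a producer excretes a toxic metabolic by-product that a
    cross-feeder consumes (food traded for detoxification). Discrete cells grow
    on Monod kinetics, divide, and shove for space above an inert substratum,
    while nutrient and by-product fields are solved to quasi-steady state by a
    sparse reaction-diffusion solver. Ships a scenario catalogue (toxicity by
    obligacy grids, microcolony seeding geometries, diffusion sweeps), a
    trajectory engine, and the analysis statistics used to characterise such
    communities: neighborhood segregation index, coculture-versus-monoculture
    interaction classification, community productivity, producer-frequency
    dynamics, near/far lineage advantage, and replicate density correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
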