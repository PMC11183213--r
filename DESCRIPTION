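Package: psfisim
Title: Stochastic Lattice Simulation of Plant-Soil Feedback Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic grid-based simulator of plant community dynamics
    driven by plant-soil feedback interactions (PSFI). Plants condition the
    soil of their cell; the conditioning species determines the growth rate
    of the cell's next occupant. The package builds interaction tables for
    modular, nested and intransitive-ring network architectures with
    positive or negative heterospecific effects and optional negative
    conspecific feedback, runs replicated lattice simulations with
    immigration, biomass-weighted recruitment, capped multiplicative growth
    and mortality, performs invasion experiments, and computes community
    invasibility, inverse Simpson diversity, Bray-Curtis compositional
    change and resident-community productivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
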