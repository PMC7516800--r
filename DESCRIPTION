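Package: isingphi
Title: Integrated Information and Criticality in Generalized Ising Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying integrated information as an order parameter
    in the generalized Ising model on small weighted networks. Generates
    ensembles of random normalized connectivity matrices, runs seeded
    Metropolis Monte-Carlo simulations (sequential and synchronous update
    schemes), derives the exact state-by-node and state-by-state transition
    probability matrices of the synchronous dynamics, computes IIT 3.0
    integrated conceptual information (Phi) per system state with an exact
    earth-mover-distance backend, and locates critical temperatures from the
    peaks of magnetic and generalized susceptibility curves across
    temperature sweeps. An exact-enumeration canonical-ensemble oracle is
    included for validating the stochastic machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
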