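Package: pushpast
Title: Survivorship Biases in Homogeneous Birth-Death Models of Clade
    Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact probability machinery for the constant-rate birth-death
    model of clade diversification conditioned on survival and on
    present-day species richness. Provides the zero-truncated geometric
    clade-size law and the conditioned distributions of standing diversity
    and of surviving-lineage counts through time, maximum-likelihood
    speciation-rate estimation, "push of the past" initial diversification
    rates, crown-group origin-time densities, large-clade-effect
    magnitudes, post-mass-extinction re-radiation expectations, and a
    forward Gillespie tree simulator with Newick export that serves as a
    Monte Carlo cross-check for the analytic results. All probability mass
    arithmetic is carried out in log space so that clades of 10,000 or
    more species remain tractable.
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
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
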