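Package: spkmix
Title: Poisson-Mixture Stationary Distributions of Gene Regulatory Networks
    with Slow Promoter Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic characterization of multimodality in stochastic gene
    regulatory networks when transcription-factor binding and unbinding are
    slow relative to protein production and decay. From a declarative network
    model the package computes the slow-promoter-kinetics limit of the
    chemical master equation: the stationary distribution is an exact mixture
    of product-Poisson components, one per global promoter configuration,
    with weights given by the stationary law of a reduced finite Markov chain
    over promoter configurations. Includes finite-state-projection solvers,
    an exact Gillespie simulator, deterministic mass-action steady-state
    analysis for comparison, and a library of canonical circuits (bursting
    gene, self-regulating gene, toggle switch, communicating toggle-switch
    populations, repressilator, trans-differentiation networks).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    deSolve,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
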