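Package: bymweights
Title: Spatial Weights Matrix Comparison for Bayesian Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the specification of the spatial weights
    matrix affects Bayesian disease-mapping inference. Builds seventeen
    weights matrices across four families (adjacency, geographic distance,
    covariate distance, and hybrid), fits the Besag-York-Mollie (BYM)
    Poisson log-linear model with an intrinsic conditional autoregressive
    (ICAR) structured effect by Markov chain Monte Carlo, applies an
    excess-variation rebalancing to restore identifiability of the two
    random effects, generates synthetic areal data sets from Gaussian
    Markov random fields on a lattice, and evaluates model fit with the
    DIC3 information criterion and permutation tests of Moran's I on
    residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
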