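Package: comrank
Title: Joint Inference of Community and Hierarchy Structure in Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of directed weighted networks in which each
    node latently prefers either community-based interactions (a mixed-membership
    stochastic block model with Poisson edge counts) or hierarchy-based
    interactions (a SpringRank-style ranking mechanism). Node preferences are
    binary latent variables; in-group edges follow the preferred mechanism and
    out-group edges occur at a small constant rate. Fitting is by variational
    expectation-maximisation with a mean-field Ising approximation of the
    node-type posterior. Includes a synthetic-network sampler with planted
    communities and Gaussian score leagues, cross-validated edge prediction,
    node-type classification, structure-recovery metrics, and a command-line
    interface for generate/fit/evaluate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
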