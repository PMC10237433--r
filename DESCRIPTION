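Package: pavbias
Title: Pavlovian Bias in the Orthogonalized Go/No-Go Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of the
    orthogonalized go/no-go task used to measure Pavlovian bias, the innate
    coupling of action to valence that conflicts with instrumental
    requirements in half of the task's conditions. Implements three
    Rescorla-Wagner action-weight models (with go bias, irreducible noise,
    and single or valence-specific outcome-sensitivity and Pavlovian-bias
    parameters), generative simulation of two-group studies, hierarchical
    Bayesian estimation with non-centered parameterization and split-Rhat
    diagnostics, PSIS-LOO model comparison, one-step-ahead posterior
    prediction, posterior group differences with highest density intervals,
    and the behavioral Pavlovian-bias indices.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
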