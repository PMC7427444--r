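Package: ergmaudit
Title: Misspecification Audits for Exponential Random Graph Models of
    Brain Functional Connectivity
Version: 0.1.0
Authors@R:
    person("ergmaudit", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits nested exponential random graph models (ERGM) to binary
    functional brain graphs with node attributes derived from structural
    connectivity, and audits the false-positive/false-negative changes in
    selective-mixing parameter estimates that arise when triadic-closure
    (geometrically weighted edgewise shared partner) and structural terms
    are omitted. Provides maximum pseudo-likelihood and Monte Carlo
    maximum-likelihood estimation with a Metropolis edge-toggle sampler,
    simulation-based goodness of fit, multinomial logistic regression of
    error rates across subject groups, and a seeded synthetic-cohort
    generator with known generative parameters for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    cluster,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
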