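Package: mratio
Title: Metacognitive Efficiency from Signal Detection Theory: meta-d',
    M-ratio, and Hierarchical Bayesian Group Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating metacognitive efficiency (meta-d'/d',
    the M-ratio) from trial-level rating data in two-alternative tasks.
    Implements type-1 and type-2 signal detection computations,
    single-subject maximum-likelihood meta-d' fitting, and a hierarchical
    Bayesian model of log M-ratio with a two-way mixed design
    (between-participant instruction by within-participant difficulty),
    sampled by an adaptive Metropolis-within-Gibbs MCMC with
    rank-normalized split R-hat and tail effective sample size
    diagnostics, highest-density intervals, and probability-of-direction
    summaries. Includes the accompanying behavioral statistics (trial and
    participant exclusion rules, mixed-design ANOVA with generalized eta
    squared, paired t tests with Jeffreys-Zellner-Siow Bayes factors,
    Levene's test with Holm correction), a generative task simulator for
    a delayed match-to-sample design with binary pre-ratings and 5-point
    post-ratings, and a reproducible end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
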