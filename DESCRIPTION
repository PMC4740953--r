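Package: hlba
Title: Hierarchical Bayesian Linear Ballistic Accumulator Modelling with
    Brain-Behavior Linking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Linear Ballistic Accumulator (LBA) model of two-choice
    response times hierarchically to two groups of subjects using
    differential-evolution Markov chain Monte Carlo (DE-MCMC), with
    positive-truncated normal hyperdistributions over every subject-level
    parameter.  Provides the LBA first-passage densities and a forward
    simulator, a posterior odds-ratio (probability-of-superiority) statistic
    for comparing group-level drift-rate hyperdistributions, Spearman rank
    correlation of individual-level posterior medians with region-of-interest
    activation values, and a synthetic-cohort generator that emulates a
    facial-emotion-identification study design (two groups, FACE and OVAL
    trials, ROI percent-signal-change tables with a controlled monotone
    association to drift rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
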