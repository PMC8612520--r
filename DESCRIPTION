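Package: coopgames
Title: Phylogenetic Multinomial Regression for Cross-Cultural Game Goal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how the goal structures of traditional
    rule-based games (solitary, competitive, cooperative) covary with
    socio-ecological attributes of the ethnolinguistic groups that play
    them. Provides filtering and recoding of game records, pruning of a
    language phylogeny and construction of the Brownian-motion
    variance-covariance matrix, Bayesian multinomial-logit regression of
    per-group category counts on binary cultural covariates with and
    without phylogenetically correlated random effects (sampled with
    JAGS), WAIC model comparison with normalized weights, and a
    synthetic-study generator for parameter-recovery and coverage
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    coda,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
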