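Package: molexplore
Title: Test-Time Training of Chemical Language Models for Multi-Target
    Chemical Space Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A SMILES chemical language model (recurrent next-token policy)
    optimized at test time by a REINFORCE policy gradient with
    prior-regularized reward reshaping, prioritized experience replay,
    random network distillation exploration bonuses and diversity filters.
    Provides a multi-target rediscovery benchmark (product of per-target
    maximum similarity, sphere-exclusion diversity), population-based
    cooperative strategies, and scaling experiments over agent counts and
    sampling budgets, together with seeded synthetic corpora and tasks for
    desk-scale evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ChemmineOB,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
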