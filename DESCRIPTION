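Package: istg
Title: Bayesian Modelling of Information Sampling in the Trust Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational models of sequential social information sampling
    in the Information Sampling Trust Game (ISTG). Implements a
    beta-Bernoulli belief-updating ("Uncertainty") stopping model together
    with three competitor policies (Sample Cost, Threshold, Count), fits
    them per subject by multistart maximum likelihood, compares them with
    BIC, bootstrap confidence intervals and random-effects Bayesian model
    selection, and relates model-derived metrics (prior belief, prior
    belief uncertainty, uncertainty tolerance, decision noise) to age with
    robust regressions. An age-structured synthetic-cohort generator makes
    the whole pipeline testable without human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lhs,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
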