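Package: rsafocus
Title: Rational Speech Act Models of Narrow-Focus Exhaustivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Rational Speech Act (RSA) models of the exhaustive
    interpretation of narrow-focus answers to wh-questions, including a
    closed-form expression for exhaustivity under binomial state priors and
    cost, exclusive-alternative, and collapsed-state model variants.
    Hierarchical Bayesian logit-normal models for slider-elicited prior and
    posterior state beliefs are fitted by an adaptive Markov chain Monte
    Carlo sampler, with posterior-predictive intervals and p-values.  A
    seeded synthetic-data generator emulates two slider-rating experiment
    designs (one slider per state, and a two-slider exhaustive versus pooled
    non-exhaustive design with prior-wording manipulations), and an analysis
    pipeline applies exclusion rules, normalization, exhaustivity summaries,
    analysis-of-variance effect tests, and a two-individual Bayes-consistency
    check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
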