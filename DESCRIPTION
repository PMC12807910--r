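Package: tvatoj
Title: Hierarchical Bayesian TVA Analysis of Temporal-Order Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates attentional capacity (C) and attentional weight (w)
    from temporal-order judgment (TOJ) data using the exponential race model
    of the Theory of Visual Attention (TVA). Provides the closed-form
    probe-first psychometric function, a hierarchical non-centered Bayesian
    model fitted by MCMC (via JAGS), posterior condition contrasts with
    highest-density intervals and region-of-practical-equivalence (ROPE)
    evidence summaries, behavioral side-analyses (categorization contingency
    tables, careless-responder exclusion, deferred-response usage), a
    synthetic-experiment generator for validation, and a simulation-based
    Bayesian power search over sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
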