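Package: jshape
Title: Marginal Structural Models for a Four-Level Time-Varying Exposure
    and Repeated Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates population-average (marginal structural model) effects
    of a four-level time-varying exposure -- alcohol consumption categorised
    as abstainer, occasional, moderate or above-guideline -- on a repeated
    binary depression outcome (CES-D-10 screening score dichotomised at 8 or
    10), in long-format longitudinal cohorts of older adults. Provides
    CES-D-10 scoring and exposure classification, cohort exclusion
    accounting, inverse probability of treatment and censoring weighting with
    percentile trimming, standardized-mean-difference balance diagnostics,
    weighted logistic estimating equations with cluster-robust variance for
    intention-to-treat and per-protocol contrasts, interaction and
    sensitivity analyses, E-values for unmeasured confounding, and a
    longitudinal cohort simulator with a counterfactual Monte-Carlo oracle
    for the true marginal odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
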