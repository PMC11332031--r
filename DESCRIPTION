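Package: twostepr
Title: Simulation and Measurement of Model-Based Planning in Two-Step Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a gamified single-choice two-step reinforcement-learning
    task (probabilistic common/rare transitions, independently drifting Bernoulli
    reward probabilities, blocked difficulty, an optional secondary "hit" reward
    layer) played by synthetic agent populations, and implements the standard
    measurement pipeline for model-based planning: lagged stay/switch design
    construction with +/-1 effect coding, per-subject ridge-regularised logistic
    point estimates, hierarchical logistic regression with correlated random
    slopes, split-half (odd/even) reliability with the Spearman-Brown prophecy
    correction, one-way intraclass correlation for test-retest, cohort exclusion
    filters, covariate-association models, and task-design comparison harnesses
    (transition ratio, reward drifts, difficulty/order, trial number).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
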