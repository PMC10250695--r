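Package: arbitrl
Title: Dissociating Model-Based and Model-Free Control in a Three-Stage
    Markov Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a 2-choice, 3-stage Markov
    decision task used to dissociate goal-directed (model-based) and habitual
    (model-free) reinforcement learning. Provides the task environment
    (subject-specific decision trees, block schedules, probabilistic
    transitions, goal-conditional payouts, and an optimal-policy oracle), a
    SARSA model-free learner and a state-prediction-error model-based learner
    with backward planning, per-subject maximum-likelihood fitting by
    multi-restart Nelder-Mead, strategy metrics (model-based preference,
    system switching, arbitration score, choice optimality), a synthetic
    agent cohort generator with known ground truth, and standard group-level
    statistics (ANOVA/ANCOVA, paired t, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
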