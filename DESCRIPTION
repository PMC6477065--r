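Package: proalhgf
Title: Hierarchical Gaussian Filter Modelling of Probabilistic Associative Learning with Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workbench for volatile cue-outcome
    associative learning. Generates block-structured probabilistic
    associative learning (ProAL) sessions, filters binary inputs through a
    three-level binary hierarchical Gaussian filter (HGF), Rescorla-Wagner,
    and Sutton K1 learner, inverts the models per subject by MAP estimation
    with a Laplace approximation of the log model evidence, compares them by
    random-effects Bayesian model selection (expected frequencies,
    exceedance and protected exceedance probabilities, Bayesian omnibus
    risk), and runs the downstream cohort statistics: distribution
    summaries, Tukey ladder-of-powers transformation, Pearson correlation
    matrices, variance inflation factors, a suite of linear regression
    models with leave-one-out cross-validated Q2, and a mixed graphical
    model estimated by nodewise L1-penalised regression with EBIC penalty
    selection. A synthetic-cohort generator reproduces the questionnaire
    score structure and effect sizes the analysis expects, so the whole
    pipeline is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    Matrix,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
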