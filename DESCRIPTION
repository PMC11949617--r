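Package: pstlearn
Title: Q-Learning Models and Group Inference for the Probabilistic Selection Task
Version: 0.1.0
Authors@R:
    person("Alex", "Reid", email = "alex.reid@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-group experiments built on the probabilistic
    selection task: task schedule construction, Q-learning likelihoods with single
    or dual learning rates and softmax choice, forward simulation of synthetic
    cohorts, hierarchical Bayesian parameter estimation with convergence
    diagnostics, PSIS-LOO model comparison, Bayesian gamma and gaussian GLMs
    relating learning parameters to group membership or transdiagnostic symptom
    scores, stratified rank tests for raw performance, and multi-target lasso
    scoring of questionnaire batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
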