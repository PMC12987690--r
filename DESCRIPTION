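Package: mstpolicy
Title: Sparse Multi-Stage Stationary Treatment Policies with Doubly
    Robust Inference
Version: 0.1.0
Authors@R:
    person("Policy", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a sparse multi-stage stationary treatment policy
    (MSTP) from micro-randomized trial data by minimizing a doubly
    robust, augmented inverse probability weighted (AIPW) estimate of
    the negative value function under an L1 penalty and a unit-ball
    constraint, and provides valid per-coefficient inference via
    decorrelated-score one-step estimators with trajectory-bootstrap
    confidence intervals.  Includes three augmentation (Q-function)
    estimators, weighted importance sampling for variance
    stabilization, a proximal coordinate descent optimizer with
    support refitting, two benchmark simulation scenarios with
    exponentially-weighted-moving-average state dynamics, on-policy
    Monte Carlo and normalized-IPW policy evaluation, and a YAML-driven
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
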