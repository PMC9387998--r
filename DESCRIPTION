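Package: saccadom
Title: Saccadometry Simulation, Damping-Ratio Estimation and Multivariate
    Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing saccadic eye movements recorded in
    prosaccade and antisaccade tasks. Simulates cohorts of saccade
    trajectories as noisy step responses of a second-order dynamical
    system, estimates per-saccade gain, damping ratio and natural
    frequency by bounded nonlinear least squares, applies kinematic
    quality-control filters, reduces each participant to a fixed vector
    of distributional features, fits mixed-effects group/task models
    with estimated marginal means and Bonferroni-corrected contrasts,
    and classifies disease status with L2-regularised logistic
    regression (with Yeo-Johnson scaling and residual-mutual-information
    forward feature selection) and random forests, evaluated by
    tournament leave-pair-out cross-validation and the 5x2
    cross-validation combined F-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    emmeans,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
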