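Package: crtsim
Title: Hybrid Electrophysiological Modelling and Machine-Learning
    Optimization of Cardiac Resynchronization Therapy Pacing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ventricular electrical activation on synthetic
    biventricular anatomies with an anisotropic eikonal model, a fractal
    right-bundle Purkinje network (complete left bundle branch block at
    baseline) and biventricular pacing protocols; synthesizes pseudo 12-lead
    electrocardiograms and fits a global myocardial conductivity multiplier
    to a target QRS duration; extracts dyssynchrony indices (TAT95, inter-
    and intra-ventricular activation delays, pacing-site distances); scores
    the probability of response to cardiac resynchronization therapy with a
    leave-one-out cross-validated logistic classifier; and locates the left
    ventricular pacing site that maximizes that score by Gaussian-process
    Bayesian optimization over the epicardial surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    kernlab,
    jsonlite,
    optparse
Config/testthat/edition: 3
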