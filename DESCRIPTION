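Package: trajvi
Title: Bayesian Trajectory Analysis with Dirichlet Process Mixtures and
    Variational Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies latent subgroups (trajectories) in longitudinal
    data by fitting a truncated Dirichlet-process mixture of multi-target
    regression models with coordinate-ascent variational inference.
    Supports continuous and binary target variables that are conditionally
    independent given trajectory membership, per-trajectory residual
    variance posteriors, and subject-level random effects with
    unstructured covariance for continuous targets.  Includes tools for
    data-informed prior specification, prior and posterior visualisation,
    model summarisation, out-of-sample trajectory assignment, a synthetic
    cohort generator, and command-line entry points covering the full
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
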