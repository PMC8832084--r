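Package: effortdm
Title: Effort-Based Decision Making for Reward: Simulation, Choice Modelling
    and Group Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying effort-based decision making for reward in
    developmental cohorts. Simulates seeded synthetic cohorts performing a
    3x3 (reward x effort) physical-effort acceptance task, fits a family of
    hierarchical Bayesian lapse-logistic choice models (via JAGS) with
    WAIC-based model comparison, derives per-trial subjective reward, effort
    and cost-benefit modulators, builds HRF-convolved first-level fMRI design
    matrices and spherical region-of-interest masks, extracts ROI contrast
    estimates by ordinary least squares, and provides the group-level
    statistics used in this literature: pooled and covariate-adjusted group
    tests with Cohen's d, Benjamini-Hochberg correction, mixed-design ANOVA
    with Greenhouse-Geisser correction, Pearson correlations with Fisher r-to-z
    group comparison, two-sample t-test power, and longitudinal regression
    models predicting follow-up internalizing symptoms from baseline symptoms
    and ROI activation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    rjags,
    coda,
    car,
    jsonlite,
    yaml,
    withr,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    broom
Config/testthat/edition: 3
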