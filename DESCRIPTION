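Package: denovofmri
Title: Simulation and Analysis of Performance-Coupled fMRI During De Novo
    Visuomotor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how task performance couples to striatal BOLD
    activity while people learn an arbitrary 14-channel glove-to-cursor mapping.
    Provides the task geometry (PCA-fitted hand-to-cursor mapping, 5x5 grid
    indexing, target sequences, trial success rates), a seeded generator for
    synthetic behavior and 4D BOLD phantoms with known parametric coupling,
    GLM design construction (double-gamma HRF, mean-centered parametric
    modulation, condition boxcars, polynomial drift, motion censoring),
    voxel-wise subject and group statistics with Monte-Carlo cluster-extent
    calibration, ROC-based spatial selectivity against anatomical masks, and
    the behavioral block statistics (paired t, two-way repeated-measures
    ANOVA with partial eta-squared).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
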