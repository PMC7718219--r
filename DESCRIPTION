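Package: fcfingerprint
Title: Individual Variability and Fingerprinting of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying individual variability in parcel-level
    functional connectomes, developed around awake mouse resting-state fMRI
    cohorts. Implements motion-based frame censoring (framewise displacement and
    DVARS rules with mask augmentation and run/session exclusion), Fisher
    z-transformed connectome construction with frame-balanced session
    splitting, network similarity and connectome-based identification with
    permutation nulls, edgewise group-consistency (Phi) and differential-power
    (DP) statistics, sessions-per-connectome subsampling, and connectome-based
    predictive modelling (CPM) of behaviour with leave-one-out cross-validation
    and shuffle-based significance. A synthetic-cohort generator with a
    group/individual/session variance decomposition, censorable motion traces
    and behaviour coupled to planted edges makes every stage testable without
    imaging data.
License: MIT + file LICENSE
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
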