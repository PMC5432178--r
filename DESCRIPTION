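Package: restfc
Title: Seed-Based Resting-State Functional Connectivity and
    Connectivity-Behavior Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for seed-based resting-state fMRI functional
    connectivity analysis and its link to behavior: nuisance regression
    with a Friston-style motion expansion, band-pass filtering of BOLD
    time series, framewise-displacement motion scrubbing with a
    minimum-duration exclusion rule, spherical ROI extraction via first
    eigenvariates, Fisher-z ROI-to-ROI and seed-to-voxel connectivity,
    hemispheric laterality indices, reaction-time cleaning and
    normalization for semantic priming tasks, and an inferential layer
    (Lilliefors normality gating, t-based correlation tests, Bonferroni
    control, repeated-measures ANOVA with Greenhouse-Geisser correction,
    signed-rank tests, and a permutation test for condition differences
    in correlation strength). Includes a seeded synthetic-data module
    that generates BOLD phantoms, tissue maps, motion traces and
    behavioral cohorts with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    car,
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'phantom.R'
    'cohort.R'
    'connectivity.R'
    'stats.R'
    'preprocess.R'
    'pipeline.R'
    'show-methods.R'
    'write-dataset.R'
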