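Package: dmnscreen
Title: Default Mode Network Screening for Mental Sub-Health from Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for anomaly-based mental
    sub-health screening from resting-state BOLD fMRI. Builds a labeled
    structural-functional default mode network (DMN) template by intersecting
    a four-region structural atlas with an ICA-derived, z-thresholded
    functional mask; extracts the six pairwise Pearson correlations among
    region-mean time series as subject features; detects anomalous subjects
    with a two-fold support vector machine (a one-class SVM bootstrap refined
    by iterated two-class SVM self-training); and maps group differences with
    voxelwise seed-based functional connectivity, regional homogeneity
    (Kendall's coefficient of concordance), and fractional amplitude of
    low-frequency fluctuation, thresholded by cluster extent. Ships a
    ground-truth synthetic 4D BOLD generator so every stage can be validated
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    e1071,
    RNifti,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
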