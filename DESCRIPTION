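Package: wmiem
Title: Inverted Encoding Models of Spatial Working Memory Under Distraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for model-based fMRI studies of
    spatial working memory. Implements an inverted encoding model (IEM) of
    polar angle with channel-basis forward mapping, least-squares weight
    estimation and inversion, reconstruction on a circular grid, fidelity and
    circular-mean decoding metrics, epoch averaging, leave-one-run-out
    cross-temporal generalization, neural-behavioral coupling analyses, and
    permutation-based inference (repeated-measures ANOVAs, paired t-tests,
    shuffled-training-label fidelity nulls, FDR correction). A synthetic-data
    module generates counterbalanced memory-guided saccade trial designs,
    spatially tuned voxel populations, hemodynamically smoothed BOLD-like
    time series, adaptive-staircase behavior, and 500 Hz gaze traces with
    ground truth, so every analysis stage is testable without scanner data.
    Includes velocity-threshold saccade detection and trial scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
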