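Package: tugseg
Title: Subtask Segmentation of the Timed Up-and-Go Test from Skeleton Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the Timed Up-and-Go (TUG) clinical mobility test into its
    subtasks (sit-to-stand, walk, turn, walk back, stand-to-sit) from RGB-D
    skeleton joint trajectories. Provides readers and writers for skeleton
    trajectory recordings and expert event labels, a synthetic TUG trial
    simulator with group-dependent timing, preprocessing (zero-phase Butterworth
    low-pass filtering, min-max normalization, walking-axis alignment), a
    dilated temporal convolutional network frame classifier implemented on base
    matrix operations, order-constrained dynamic-programming label correction
    against the canonical subtask sequence, six-event extraction, and an
    evaluation suite (per-subtask precision/recall/F1, frame accuracy, event
    timing errors, total TUG time error, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
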