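Package: segrankloss
Title: Rank-Based Loss Aggregation for Segmentation Under Annotation Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loss-aggregation envelope for multi-class semantic segmentation
    trained from boundary-noisy pixel annotations. Implements rank-based
    image-level selection (average top-k and its decreasing schedule) with
    sigmoid-smoothed boxcar selector weights, a statistics-based "bottom all
    but sigma" pixel filter, combined cross-entropy plus continuous-Dice
    per-pixel losses, a synthetic noisy-annotation dataset generator with a
    homogenization control, a desk-scale training and ablation harness, and
    standard segmentation metrics (accuracy, Dice, mIoU, HD95).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
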