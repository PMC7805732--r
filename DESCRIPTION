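Package: kneemoments
Title: Automated Knee Osteoarthritis Grading from Radiographs with Hu
    Invariant Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic Kellgren-Lawrence (KL)
    grading of knee osteoarthritis from plain radiographs. The joint-space
    region of interest is located from the row-wise pixel-density profile,
    segmented with a region-based (two-phase piecewise-constant) active
    contour, and summarised by Hu's seven invariant moments, which are
    graded with a k-nearest-neighbour classifier under stratified two-fold
    cross-validation. Includes a deterministic synthetic knee-phantom
    generator for testing every stage without clinical images, multiclass
    confusion-matrix metrics in both the standard and the
    expert-denominator conventions, and inter-rater agreement statistics
    (goodness-of-fit chi-square on per-grade counts and the paired t test
    on count differences).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
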