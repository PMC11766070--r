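Package: lesionwise
Title: Component-Based Evaluation of Brain MRI Lesion Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates 3D brain-MRI abnormality segmentations against reference
    ground truth both as whole volumes (Dice similarity coefficient, sensitivity,
    precision, volume strata, volume correlation) and lesion by lesion: connected
    components of the ground-truth and detection masks are matched through their
    voxel overlap, scored with a per-component Dice coefficient, and classified
    as Found, Partially Found, or Missed on each side. Components are further
    profiled by position relative to the brain center and by their intensity
    difference versus a healthy white-matter reference region across MRI
    modalities (FLAIR, T2, T1ce). A seeded phantom generator produces synthetic
    multi-lesion case bundles with known per-component volume, position,
    intensity contrast, and target Dice, so every statistic the package reports
    can be validated against a known truth without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
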