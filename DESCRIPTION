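Package: ramplux
Title: Analysis of Calcium-Imaging Responses to Slow Luminance Ramps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for analysing GCaMP calcium-imaging
    responses to slow triangular luminance-ramp stimuli in the larval
    zebrafish visual system. Provides deterministic stimulus models
    (whole-field ramps and receptive-field mapping checkerboards), z-score
    normalisation and responsiveness gating of fluorescence traces,
    cycle-averaged response extraction, significant-peak detection by
    topographic prominence with LUX-at-half-max and width-at-half-max
    kinetics, supervised (linear SVM, cross-validated) and unsupervised
    (k-means with Calinski-Harabasz elbow selection) classification into
    ON/OFF/DUAL/nonresponsive classes, activity-threshold segmentation of
    calcium movies into ROIs with active-area fractions and layer tallies,
    and binocular receptive-field mapping with size, contra/ipsi ratio and
    tier comparisons. A synthetic-data module generates labelled traces,
    movies with known active regions and convergent receptive-field scenes
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
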