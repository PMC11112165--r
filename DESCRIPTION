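Package: eecdynamics
Title: Quantitative Analysis of Enteroendocrine Cell Calcium Dynamics in 4D Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying enteroendocrine cell (EEC)
    cytoplasmic and mitochondrial calcium dynamics from two-channel 3D time-lapse
    fluorescence microscopy of the larval zebrafish intestine. Provides a
    ground-truthed synthetic time-lapse generator, per-frame 3D segmentation
    (Gaussian smoothing, automatic thresholding, size filtering, watershed
    separation), optimal-assignment object tracking, per-cell trace extraction and
    normalization, spontaneous-activity and stimulus-responder classification,
    response amplitude and sustained-elevation metrics, hierarchical clustering of
    temporal dynamics, intracellular mitochondrial distribution profiling, and
    dual-contrast differential-expression quadrant statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
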