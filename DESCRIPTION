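Package: spikeobb
Title: Oriented Bounding-Box Tools for Crop Spike Detection in UAV Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry, label encoding, losses and evaluation metrics for
    oriented (rotated) bounding-box detection of elongated crop organs such as
    sorghum spikes in UAV imagery. Provides exact rotated-box intersection by
    convex polygon clipping with triangulated areas, circular smooth label
    (CSL) angle encoding over 180 one-degree categories, a Wise-IoU
    localization loss, oriented non-maximum suppression driven by the
    overlap-to-area-sum ratio, detection/angle/count evaluation metrics
    (mAP, RMSEa, MAEa, RMSE, MAE), annotation-aware augmentation and tiling,
    readers and writers for roLabelImg XML and DOTA-style text annotations,
    and a synthetic spike-scene generator so every component is testable
    without a field dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    grDevices,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble,
    withr,
    xml2
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
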