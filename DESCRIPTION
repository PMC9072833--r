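Package: phenosdm
Title: Deep Species Distribution Models from Satellite Image Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully offline pipeline for studying how much the
    temporal (seasonal) dimension of satellite image time-series contributes to
    deep species distribution models. Includes a synthetic-world generator
    (tiled monthly multispectral rasters with habitat-specific seasonal
    signatures, clouds, a long-tailed species pool and spatially biased
    occurrence sampling), a dataset-construction workflow (greedy tile cover,
    least-cloudy monthly product selection, patch extraction and channel
    stacking), spatial-block stratified splitting, a compact convolutional
    classifier trained with the label-distribution-aware margin (LDAM) loss and
    deferred re-weighting (DRW), imbalance-aware top-k evaluation statistics
    (micro/macro/per-region accuracies, Hill diversity numbers), and temporal
    ablation experiments (month permutation, temporal averaging, single-month
    sampling) with relative performance-change statistics and paired tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    withr,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
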