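Package: uamt3d
Title: Uncertainty-Aware Mean-Teacher Semi-Supervised 3D Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised volumetric segmentation with an uncertainty-aware
    mean-teacher framework: a residual, attention-augmented (CBAM) 3D U-Net
    backbone, exponential-moving-average teacher updates, Monte-Carlo-dropout
    entropy uncertainty, and an uncertainty-gated consistency loss on unlabeled
    volumes. Includes a reproducible synthetic CT/CBCT-like phantom generator,
    NIfTI volume input/output, sliding-window whole-volume inference, and
    overlap/surface-distance evaluation metrics (Dice, Jaccard, 95th-percentile
    Hausdorff distance, average surface distance) with relative-change
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
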