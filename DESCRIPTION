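Package: brightseg
Title: Self-Training Cell Segmentation for Label-Free Bright-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains a fully convolutional network to segment unstained cells in
    bright-field microscopy using training labels generated automatically from
    end-point fluorescence staining, so that no manual annotation is required.
    Provides a synthetic microscopy scene simulator with known instance ground
    truth, iterative spline-surface illumination correction, fluorescence-based
    instance label generation (global thresholding, watershed declumping and
    seeded region growing), patch augmentation with class-balanced pixel
    weights, a compact encoder-decoder network with residual bottleneck and
    long skip connections trained with a weighted softmax loss and RMSProp,
    artifact-free two-pass Gaussian-blended tiled inference, watershed-based
    instance extraction with label-safe dilation, and per-cell F-score
    evaluation with cumulative curves and per-site summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    rlang,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
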