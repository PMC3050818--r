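Package: livingarray
Title: Single-Cell Reporter Dynamics from Living-Microarray Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying transcriptional induction in single cells
    imaged on reverse-transfection cell microarrays. Provides spot-grid
    registration of slide overview images (lens-distortion correction, disk
    convolution and watershed spot detection, affine mapping to stage
    coordinates), cubic focus-surface interpolation with RANSAC outlier
    rejection and an autocorrelation focus score, nuclear segmentation of
    dual-channel (inducible Venus / constitutive ECFP) time-lapse stacks by
    Fourier low-pass filtering and watershed, two-phase (strict, then
    flexible gap-closing) single-cell tracking, and downstream statistics:
    ECFP-normalized induction profiles, responder calling, fold-change
    distributions and replicate subsampling. A synthetic movie generator
    with complete ground truth (masks, correspondences, per-cell induction
    parameters) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
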