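Package: fovealCT
Title: Foveal 3D Fully Convolutional Detection and Segmentation of
    Lymph-Node-Like Lesions in Thoracic CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and whole-volume segmentation of lymph-node-like
    lesions in thoracic CT volumes with a three-dimensional foveal fully
    convolutional network (f-net).  The network receives a multiscale
    pyramid of co-centered image patches, processes each resolution level
    in a pathway of valid convolution / batch normalization / ReLU (CBR)
    blocks, integrates the levels coarse-to-fine with upsampling, and
    emits a per-voxel class probability map that is thresholded and
    decomposed into connected components.  The package covers the full
    pipeline: NIfTI/MetaImage volume handling, isotropic resampling,
    Hounsfield-unit windowing with automatic window estimation, lesion
    aware patch sampling, bounded on-the-fly augmentation, cross-entropy
    training with AdaDelta, Dice-optimal threshold selection, tiled
    whole-volume inference, component-level detection metrics with
    short-axis-diameter stratification, bootstrap variability and rate
    comparison, and a synthetic CT phantom generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
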