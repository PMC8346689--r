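Package: brainseg3d
Title: Spatial-Prior-Augmented 3D U-Net Segmentation of Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for multiclass brain tissue
    segmentation of T1-weighted MRI: synthetic brain phantom generation,
    NIfTI preprocessing (foreground crop, cubic resampling, z-score
    normalization, random affine augmentation, native-space inversion),
    three-stage rigid/affine/deformable registration for construction of
    patient-specific spatial priors by template label propagation, a 3D
    U-Net with context/localization blocks, instance normalization and
    deep supervision trained with soft Dice or (weighted) categorical
    cross-entropy, and an evaluation suite (Dice, volume similarity,
    95th-percentile Hausdorff distance, intra-lesion accuracy, two-sample
    Z comparisons). The network and registration engines are implemented
    in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
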