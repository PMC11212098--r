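Package: gliomafuse
Title: Multimodal MRI Glioma Grading by Fusing a 2D CNN with 3D Tumor
    Shape Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for binary glioma grading (low-grade
    versus high-grade) from co-registered multimodal MRI (T1, T2, T1-Gd,
    FLAIR) with a BraTS-style tumor segmentation. Tumor-masked axial
    slices feed a four-channel convolutional classifier whose image
    features are projected to 14 values and fused with 14 explicitly
    computed 3D radiomic shape descriptors (mesh and voxel volume,
    surface area, sphericity, maximum 3D/2D diameters, principal axis
    lengths, elongation, flatness); slice-level class probabilities are
    averaged per patient. Includes a synthetic phantom cohort generator,
    class-imbalance augmentation (flips, cyclic shift, rotation, salt
    and pepper noise), AUC / accuracy / average per-class accuracy /
    sensitivity / specificity evaluation, Kaplan-Meier and log-rank
    survival analysis with a trimmed-mean imputation rule, and
    gradient-weighted class-activation heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    png,
    survival,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
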