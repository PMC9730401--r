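Package: parotidseg
Title: Attention U-Net Autosegmentation of Parotid Glands and Tumors on
    Multi-Sequence MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for automatic segmentation of the left and
    right parotid glands and the tumors embedded in them on co-registered
    multi-sequence MR images (T1-weighted, T2-weighted and contrast-enhanced
    T1-weighted). Implements a 2D U-Net with attention gates on the skip
    connections whose gating signal is drawn from the network bottleneck,
    trained with a soft-Dice (1 - DICE) loss under RMSprop, with gray-level,
    affine and left/right mirroring (with lateral label swap) augmentation,
    patient-level k-fold cross-validation, and a four-metric evaluation suite
    (DICE, JACCARD, 95th-percentile and average Hausdorff surface distances
    on the anisotropic voxel grid). A synthetic phantom generator provides
    reproducible multi-sequence volumes with paired masks so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
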