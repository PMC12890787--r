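Package: bundleseg
Title: Brainstem White-Matter Bundle Segmentation from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation of brainstem white-matter bundles from
    diffusion MRI. Builds a three-channel probabilistic fiber map from
    region-of-interest-pair probabilistic tractography, feeds it with low-b and
    fractional-anisotropy channels into an attention-gated five-level 3D U-Net,
    and refines the per-voxel label probabilities with a semidense conditional
    random field solved by fixed-iteration mean-field updates. Includes a
    ground-truthed tubular bundle phantom generator, diffusion tensor fitting
    and scalar maps, and the evaluation machinery used for validation: Dice,
    average Hausdorff distance, two-way mixed-effects intraclass correlation,
    leave-one-out linear discriminant ROC-AUC, and rank-based group comparison
    with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
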