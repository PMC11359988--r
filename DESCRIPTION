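Package: swinreg
Title: Anatomically Constrained Swin-Transformer Rigid Registration for
    Head-Neck CT/CBCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weakly supervised rigid registration of head-neck cone-beam CT
    (CBCT) to planning CT for image-guided radiotherapy. A 3D Swin-Transformer
    regression network predicts the six rigid parameters (translation in mm,
    rotation in degrees); training is driven by a perceptual similarity loss
    built from a pretrained 3D denoising autoencoder, plus anatomical
    constraint losses (soft Dice and an encoded global segmentation distance)
    that bias accuracy toward the head region. Includes NIfTI volume I/O and
    preprocessing, differentiable rigid warping, a seeded synthetic head-neck
    phantom generator with CBCT-style degradation and neck-only deformation,
    evaluation metrics (Dice, 3D SSIM, region-stratified landmark target
    registration error), a training/evaluation pipeline and a command-line
    interface. All tensor computation runs on a built-in reverse-mode
    autodifferentiation tape with compiled convolution and resampling kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
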