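Package: cordfuse
Title: Two-Stage Multi-Atlas Spinal Cord and Grey Matter Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated slice-wise segmentation of the cervical spinal cord
    and its grey matter from axial MR images using two chained multi-atlas label
    fusion stages: a PatchMatch-based localiser that roughly segments the cord
    from a template library, and a STAPLE-type expectation-maximisation fusion
    with local normalised cross-correlation template selection (STEPS) fed by
    slice-wise block-matching affine and B-spline free-form registrations.
    Includes a seeded synthetic spinal-cord phantom generator, a template
    library manager with left-right flip augmentation, and the standard
    evaluation protocol (majority-vote consensus, rater screening,
    leave-one-out cross-validation, Dice, surface distances, cross-sectional
    area and coefficient of variation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
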