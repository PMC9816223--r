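Package: axialseg
Title: Deformable-Model Augmentation and Gated Axial-Attention Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data augmentation for 2D medical image segmentation by a
    statistical shape model (point distribution model) combined with
    thin-plate-spline texture transfer, and a dual-branch (global/local)
    segmentation network built on gated axial self-attention, trained with
    binary cross-entropy. Includes generalized Procrustes alignment,
    shape sampling within an eigenvalue-scaled hyperrectangle, polygon
    rasterization of contours, a seeded synthetic fixture generator,
    a CPU training loop with Adam, and Dice/IoU/Recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mgcv,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
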