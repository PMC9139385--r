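Package: biplanar3d
Title: 3D Spine Reconstruction from Simulated Bi-Planar Radiographs with a Conditional GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing a three-dimensional binary spine volume
    from two orthogonal (anteroposterior and lateral) simulated radiographs.
    Provides a procedural spine CT phantom generator with paired ground-truth
    segmentations, an empirical Hounsfield-unit bone-signal enhancement
    algorithm, a parallel-beam digitally-reconstructed-radiograph projector,
    a conditional least-squares GAN (dual-view 2D encoder, fused 3D decoder,
    3D patch discriminator) with a pure-R/Rcpp training engine, volumetric
    overlap metrics (Dice, Jaccard, overlap volume) and projection SSIM, and
    a k-fold cross-validation harness with rank-based statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
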