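Package: fastdmsa
Title: Acquisition-Time Reduction for Pediatric Renal Planar Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workflow for reducing the acquisition
    time of pediatric 99mTc-DMSA planar scintigraphy with convolutional
    denoising networks. Provides a seeded dynamic-phantom generator with
    known kidney geometry and ground-truth uptake, rigid frame registration
    by iterative mean-squared-error minimization, construction of
    short-time/full-time frame-sum training pairs, three residual denoising
    architectures (DnCNN, Win5RB, ResUnet) with a compiled convolution
    engine and Adam training, image-quality metrics (NMSE, PSNR, SSIM,
    joint voxel-wise histograms), and ROI-based renal uptake quantification
    with Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
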