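Package: PATRecon
Title: Photoacoustic Tomography Reconstruction from Undersampled
    Compressed-Sensing Measurements
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing two-dimensional photoacoustic
    tomography (PAT) images from heavily undersampled linear measurements.
    Provides random Gaussian and physical ring-array measurement operators
    (time- and frequency-domain kernels), a Monte-Carlo restricted-isometry
    diagnostic, a total-variation-regularised least-squares baseline solved
    by monotone accelerated proximal gradient, and a learned reconstruction
    pipeline in which a fixed transpose-operator proxy stage is followed by
    a convolutional network (3-layer CNN, U-Net, or residual U-Net) trained
    with an L1 loss and the Adam optimiser. Includes a synthetic
    mouse-cross-section phantom generator, augmentation and normalisation
    utilities, SSIM/PSNR quality metrics implemented from first principles,
    and an end-to-end benchmark that aggregates mean and standard deviation
    of the metrics per method and undersampling ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
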