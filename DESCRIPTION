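Package: fpmdetect
Title: Fourier Ptychographic Microscopy Simulation, Reconstruction and
    White-Blood-Cell Detection on Synthetic Blood Smears
Version: 0.1.0
Authors@R:
    person("FPM", "Detect Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained workbench for computational microscopy of
    blood smears. Simulates Fourier ptychographic microscopy (FPM)
    acquisition of synthetic stained-smear phantoms under angled LED
    illumination, reconstructs high-resolution wide-field complex images
    by iterative frequency-domain sub-aperture stitching, and detects
    white-blood-cell-like targets with a small set-prediction
    (transformer encoder-decoder) detector featuring an average-pool
    downsampling residual block and a complete-IoU bounding-box loss.
    Includes a DCGAN for 1:1 augmentation of cell crops, COCO-style
    annotation handling, mean-average-precision evaluation, and a
    command-line pipeline. All neural components run on a compact
    tape-based automatic-differentiation engine with Rcpp kernels; no
    external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    png,
    digest,
    optparse
Config/testthat/edition: 3
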