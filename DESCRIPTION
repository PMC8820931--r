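Package: pyrexcam
Title: Interpretable Pyramid Scene Parsing Segmentation with Gradient-Based
    Class Activation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segments brain-tumor MRI slices with a compact pyramid scene
    parsing network (residual backbone, multiscale adaptive-pooling module,
    deconvolution decoder) and interprets the trained model with
    gradient-weighted class activation mapping (Grad-CAM) taken at the
    backbone features, at each pyramid stage, and at the concatenated
    multiscale context features.  Includes a phantom-slice generator and
    BraTS-layout NIfTI fixtures so the full pipeline is testable without
    external data, a dice/PSNR evaluation suite for binarized heat maps,
    and seeded experiment harnesses for stage-weighting and scale-count
    ablations.  The network and its backpropagation are implemented in
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
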