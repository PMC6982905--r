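Package: rodtrack
Title: Multi-Animal Detection and Tracking for Overhead Arena Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A real-time style detect-and-track toolkit for laboratory
    rodents filmed from above. Provides non-maximum suppression over scored
    bounding boxes, a per-animal constant-velocity Kalman filter, Hungarian
    identity assignment with prediction-augmented costs, nine-point
    gray-value position correction, masked specular-highlight removal by
    gradient-domain attenuation and Poisson reconstruction, an automatic
    PASCAL VOC annotation generator built on classical segmentation, and a
    synthetic arena-scene generator with ground truth so the whole pipeline
    is testable end to end without recorded video or a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Matrix,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
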