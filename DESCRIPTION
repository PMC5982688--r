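Package: weightsense
Title: Contact-Less Body Weight Estimation from RGB-D(-T) Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates human body weight without contact from depth-camera
    point clouds of lying, standing and walking subjects. Provides PCD file
    input/output with color and thermal channels, pinhole projection and
    thermal fusion, scene segmentation (region cropping, RANSAC plane
    removal, thermal thresholding, background subtraction, morphological and
    statistical cleaning), a 19-component shape descriptor (frontal-mesh
    volume and surface, scatter-matrix eigenvalue features, statistical
    moments, silhouette contour and convex-hull features), a three-layer
    feed-forward network trained by resilient propagation with weight decay
    and early stopping, robust aggregation of per-frame estimates over a
    walking sequence by mean-pairwise-distance clustering, and a synthetic
    humanoid scene generator with analytic ground-truth weight for fully
    self-contained experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
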