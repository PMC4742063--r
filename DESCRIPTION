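Package: ccp
Title: Convolution Comparison Patterns for Fingerprint Liveness Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the convolution comparison pattern (CCP) local image
    descriptor for presentation-attack (liveness) detection in fingerprint
    images.  Rotation-invariant patches are extracted with the help of an
    orientation field estimated by averaging squared image gradients, their
    two-dimensional discrete cosine transform coefficients are normalized, and
    the most discriminative coefficient comparisons are learned from labeled
    training images by exhaustive search.  Per-image histograms of the
    resulting binary patterns feed a linear support vector machine that
    classifies images as live or spoof.  A synthetic generator of oriented
    ridge-valley textures with ground-truth masks and orientation fields makes
    the whole pipeline testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    png,
    tiff,
    jsonlite,
    e1071,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
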