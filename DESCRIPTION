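Package: hsirefine
Title: Weakly Supervised Spectral-Spatial Refinement for Hyperspectral
    Land-Cover Classification
Version: 0.1.0
Authors@R:
    person("hsirefine", "maintainers", email = "maintainers@hsirefine.org",
           role = c("aut", "cre"))
Description: Pixel-wise probabilistic classification of hyperspectral
    reflectance cubes refined by iterative energy minimization that trades
    off spectral similarity against spatial nearness in a local
    neighborhood. Provides ENVI and MAT-container raster input/output,
    water-absorption band filtering, principal-component spectral
    reduction with an explained-variance threshold, a kernel probabilistic
    seed classifier with cross-validated grid search, iterated conditional
    modes label refinement with Gaussian nearness and similarity kernels,
    weak-label feedback, band-subset ensemble voting, confusion-matrix
    metrics (overall accuracy, average accuracy, Cohen's kappa), and a
    synthetic labeled-scene simulator for end-to-end testing and
    cross-scene transfer experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
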