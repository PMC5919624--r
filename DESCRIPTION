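Package: dgcurve
Title: Dose Gradient Curves for Radiotherapy Plan Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based evaluation of dose fall-off around radiotherapy
    targets. Converts a 3D dose distribution into differential and cumulative
    dose gradient curves built from the dose gradient index (DGI), the average
    distance between two nested isodose surfaces estimated from their volumes
    and surface areas. Includes marching-tetrahedra isosurface extraction with
    exact mesh area/volume, anisotropic Euclidean distance transforms for
    uniform structure expansion and body cropping, dose-volume histograms and
    the legacy gradient indices (GI, R50%), closed-form sphere/cube error
    analysis of the DGI estimator, synthetic stereotactic-radiosurgery-like
    plans with analytically known isodose geometry, NRRD/NIfTI volume I/O,
    and base-graphics plotting of the curves alone or combined with a DVH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
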