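Package: lungmech
Title: Regional Lung Mechanics from Serial Inspiratory CT via
    Mass-Preserving Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative computed tomography (QCT) assessment of regional
    lung mechanics from pairs of serial inspiratory CT scans. Implements
    the air/tissue density decomposition of Hounsfield units, non-rigid
    B-spline registration driven by the sum of squared tissue volume
    difference (SSTVD) similarity metric with a multilevel scheme,
    Jacobian-determinant maps of local volume change, normalized
    fractional volume/air/tissue change maps, threshold-based
    hyper-expansion indices, and Welch two-sample group comparisons.
    Includes a seeded digital lung phantom generator with analytically
    known deformations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
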