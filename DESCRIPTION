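Package: esaprot
Title: Elastic Shape Analysis of Protein Backbone Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats protein backbones as parameterized three-dimensional
    curves and compares them with elastic shape analysis. Curves are
    represented by square-root velocity functions on the preshape sphere;
    a proper geodesic distance between two structures is obtained by
    jointly optimizing over rotations (SVD) and reparameterizations
    (dynamic programming). Provides geodesic deformation paths, Karcher
    means, tangent-space covariance with principal-direction sweeps,
    Gaussian-type sampling of random structures, per-residue flexibility
    profiles, and distance-based hierarchical classification scored with
    the Rand index. Includes generators for backbone-like synthetic curves
    and ensembles with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
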