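Package: idest
Title: Global and Local Intrinsic Dimension Estimation for Point Clouds
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A uniform collection of global and local intrinsic dimension
    (ID) estimators for numeric data matrices, together with seeded
    generators of benchmark manifolds and a meta-analysis layer. Implements
    eigenvalue-spectrum (PCA) dimension criteria, nearest-neighbor distance
    estimators (maximum likelihood, two-nearest-neighbors, method of
    moments, manifold-adaptive dimension, tight-locality estimation,
    minimum-neighbor-distance likelihood, correlation dimension, k-NN graph
    scaling) and concentration-of-measure estimators (Fisher separability,
    expected simplex skewness, angle-and-norm concentration). Any global
    estimator can be repurposed as a local, per-point estimator over
    k-nearest-neighbor sub-clouds. The meta-analysis layer profiles
    collections of datasets across all estimators with per-method input
    caps, accounts for invalid results, imputes missing cells, and derives
    consensus dimension scores, method correlation structure, redundancy
    sensitivity ratios and a multiplicative runtime model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
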