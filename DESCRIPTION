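Package: rvrfuse
Title: Multimodal Voxel-Wise Prediction of Behaviour with Relevance
    Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds individual-level behavioural prediction models from
    multimodal voxel-wise neuroimaging features (resting-state amplitude
    of low-frequency fluctuations, gray matter volume, fractional
    anisotropy). Implements sparse Bayesian relevance vector regression
    with a linear kernel, in-fold z-normalisation and Bonferroni
    mass-univariate feature selection, prediction-averaging fusion of
    mono-modality models, leave-one-out and repeated k-fold
    cross-validation, permutation tests of prediction accuracy,
    Steiger's test for dependent correlations, and back-projection of
    kernel weights to voxel space with atlas- and network-level
    aggregation. Ships a seeded synthetic-data generator with planted
    ground truth for end-to-end validation, plus ALFF computation and
    nuisance-regression utilities for resting-state time series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
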