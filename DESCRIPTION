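Package: facegeom
Title: Multivariate Pattern Decoding and Representational Geometry for
    Face-Processing fMRI Experiments
Version: 0.1.0
Authors@R: person("famface", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding identity-independent face familiarity and face
    identity from run-wise fMRI beta patterns, and for characterizing the
    second-order representational geometry of face-processing regions.
    Implements identity-controlled cross-validation (leave-two-identities-out),
    searchlight multivariate pattern classification with a built-in linear
    C-SVM, permutation inference with threshold-free cluster enhancement
    (TFCE), cross-validated representational dissimilarity matrices over run
    partitions, classical multidimensional scaling, the RV coefficient, and a
    mixed-effects contrast of within- versus between-system RDM correlations.
    Includes a synthetic-data generator that emulates a slow event-related
    design with planted familiarity-, identity-, and view-dependent signal
    components, so the full pipeline can be exercised without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
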