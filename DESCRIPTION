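Package: rsvmcluster
Title: Random SVM Cluster Classification of Brain Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-subspace ensembles of RBF-kernel support vector machines
    ("random SVM clusters") for two-group classification of high-dimensional
    resting-state fMRI functional-connectivity data. Each member SVM is
    trained on a random subset of subjects and a random subset of pairwise
    Pearson-correlation features; predictions are combined by majority vote.
    Includes frequency-based feature importance from high-accuracy members,
    an optimal-feature-set search, per-region abnormality weights on the
    AAL-90 parcellation, demographic comparison utilities, and a synthetic
    cohort generator with planted group-differential connections so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
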