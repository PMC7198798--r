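Package: immunet
Title: Inference and Comparison of Directed Cytokine Signaling Networks
    from Exercise Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring directed, signed immune-signaling networks
    from short plasma cytokine time courses collected around a maximal
    exercise challenge. Cytokine panels are preprocessed (non-detect
    replacement, uniform-grid interpolation, log2 fold-change normalization
    to the healthy resting baseline), aggregated into functional cytokine
    sets by pooled principal components, and fitted per subject with a
    linear rate-equation model via partial least squares regression with
    broken-stick component retention. Downstream analyses include
    semi-metric time-series divergence with resampled group comparisons,
    literature-based reference network construction (cell-node collapse,
    confidence filtering, network union), subsampled consensus and
    unanimity characteristic networks, weighted graph edit distance with
    resampled significance, centrality and hub/authority profiling,
    feedforward/feedback motif classification, exhaustive in-silico
    receptor-blockade search, and qualitative fuzzy-logic dynamics
    simulation. A synthetic two-group cohort generator with known
    ground-truth networks supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
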