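Package: fcvcm
Title: Variance Component Analysis of Static and Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much inter-subject behavioral variability is
    explained by resting-state functional connectivity (FC), contrasting
    static FC (Pearson correlation) with dynamic FC (the coefficient matrix
    of a first-order autoregressive model). Provides motion scrubbing
    (FD/DVARS censoring), nuisance regression, static and dynamic FC
    estimation, inter-subject similarity kernels with network-block
    restriction and an additive block-pair decomposition, a multi-kernel
    variance component model estimated by the method of moments with a
    univariate likelihood cross-check, delete-one jackknife inference with
    Benjamini-Hochberg FDR control, and a synthetic cohort generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
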