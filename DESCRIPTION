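Package: graphsrc
Title: Graph-Regularized Sparse Representation Classification for EEG Brain-State Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse representation classification (SRC) of EEG-derived feature
    vectors with combination weights estimated by sparse Bayesian learning under
    a graph-Laplacian prior over feature interactions. Includes the companion
    EEG feature pipeline (frontal band powers from highly overlapped
    spectrograms, hemispheric asymmetry, inter-subject correlations, and a
    rank-across-products transform), a baseline L1-penalized SRC, synthetic
    generators for union-of-subspaces feature data and band-limited oscillatory
    EEG, a repeated train/test-split and repeated k-fold evaluation harness
    with confusion matrices and class-wise precision/recall, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
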