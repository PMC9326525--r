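Package: splitsim
Title: Simulation of Splitfed and Multi-Head Split Learning with Leakage
    and Communication-Cost Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for split learning of block-structured
    neural networks across several clients and one server.  Supports
    splitfed learning (splitfedv2: a single server-side model plus federated
    averaging of the client-side portions each epoch) and multi-head split
    learning (the same protocol with client-side synchronization removed),
    with the model cut at any block boundary.  Includes a deterministic CPU
    training engine for convolutional, residual and dense blocks; an
    analytic communication-size and training-time cost model reconciled
    against instrumented element counters; a plug-in mutual-information
    score estimator quantifying how much the cut-layer activations
    ("smashed data") leak about the raw inputs; seeded generators for
    synthetic multi-class 1-D signals and 1-/3-channel images emulating
    biomedical classification tasks; and experiment drivers for mode
    comparisons, cut-layer sweeps and leakage trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
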