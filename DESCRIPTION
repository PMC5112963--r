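Package: attnet
Title: Emergence of Selective Attention in Deep Belief Networks Trained on
    Context-Dependent Stimulus-Action Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation study of selective attention emerging in a stack of
    Restricted Boltzmann Machines trained with one-step contrastive divergence
    (CD-1) and per-epoch dropout on a context-dependent stimulus-to-action
    task. Provides the synthetic task generator (binary visual, context and
    action channels on 25x25 grids), greedy layer-wise training of the
    1925-300-200-100 network, depth-limited mean-field reconstruction,
    iterative generation, instructed-delay time-course simulations,
    receptive-field extraction with context-dependence classification,
    population ablations, and the full set of control conditions (training-set,
    architecture and learning-schedule variations), together with
    replication-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
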