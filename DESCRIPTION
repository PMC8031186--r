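Package: spikeTE
Title: Effective Connectivity, Cell Typing, and Controllability Analysis of
    Neuronal Spike Trains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers signed, directed effective connectivity among cortical
    neurons from millisecond-resolution spike trains using delayed transfer
    entropy with a spike-jitter surrogate null, classifies neurons as
    excitatory or inhibitory from sorted local transfer entropy via Ward
    clustering, and quantifies each neuron's topological influence through
    k-core centrality, triad motif statistics, and minimum feedback vertex
    set controllability. Includes an Izhikevich-type spiking-network
    simulator with known ground-truth connectivity for validation, and a
    rule-based assignment of cortical layers from one-dimensional cell
    density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    nortest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
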