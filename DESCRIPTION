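Package: stochsyn
Title: Stochastic Synaptic Release Networks with Presynaptic Metaplasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models layered neural networks whose synapses transmit
    stochastically: each synapse releases with a per-synapse Bernoulli
    probability that is itself learned by a metaplasticity rule driven by
    the magnitude of the strength-update direction. Release probabilities
    come to encode synaptic importance (empirical Fisher information), and
    a consolidation mechanism - learning-rate scaling by one minus the
    release probability plus freezing of high-probability synapses -
    stabilises important synapses during sequential task learning. The
    package provides the network model and learning rule, a measurement
    battery (synaptic energy, task-relevant mutual information, empirical
    Fisher information, lesion curves, neuron-level sparsity statistics),
    synthetic task generators for split/permuted/continuous lifelong
    protocols, a stochastic-release perceptron for gradient-free pattern
    memorisation, and an experiment harness with energy-efficiency and
    lifelong-learning experiments including ghost-probability and
    no-consolidation ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
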