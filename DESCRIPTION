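Package: btspcam
Title: Content-Addressable Memory with Binary Synapses via Behavioral
    Time-Scale Synaptic Plasticity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and closed-form theory of the system of memory
    traces created by a stochastic behavioral time-scale synaptic
    plasticity (BTSP) rule acting on binary synaptic weights in a sparse
    two-layer network, modelling one-shot formation of content-addressable
    memory in hippocampal area CA1.  Provides generators for sparse binary
    memory items (including controlled-overlap ensembles and line-drawing
    images), the binary BTSP learning rule and its deterministic core
    variant, feedforward recall with trace-level metrics, a binomial
    parity theory predicting firing probabilities and expected Hamming
    distances, Hopfield-network and random-projection baselines,
    Hebbian-feedback pattern completion, and the repulsion-effect
    experiment for similar memory items.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
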