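Package: mlifsnn
Title: Spiking Neural Networks with Multi-Compartment LIF Neurons and
    Dendritic Plateau-Potential Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-layer spiking neural networks of
    multi-compartment leaky integrate-and-fire (MLIF) neurons trained by a
    two-phase, dendrite-guided plasticity rule: the time-averaged apical
    dendritic potential (the plateau potential) of each hidden neuron is
    compared between a free forward phase and a nudged target phase, and
    weights are updated once per trial from that local discrepancy.
    Includes a bit-faithful emulation of the digital-circuit arithmetic
    used by neuromorphic hardware realizations of the model (24-bit
    sign-magnitude fixed point, shift-add multiplication, piecewise-linear
    sigmoid approximations, lookup-table Poisson spike generation), a
    floating-point reference backend, frequency-coded pattern
    classification and pattern-reproduction experiments, and drop-noise
    robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
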