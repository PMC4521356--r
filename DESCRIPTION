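Package: ratespike
Title: Equation-Oriented Simulation of Rate-Coded, Spiking and Hybrid Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-machine reference simulator for networks of rate-coded and
    spiking neurons. Neuron and synapse models are written as plain-text
    parameter and equation blocks (first-order ODEs, regular assignments,
    conditionals, random terms); the package parses them, builds per-step
    update rules under one of four numerical schemes (explicit, implicit and
    exponential Euler, midpoint) or exact event-driven closed forms for linear
    synaptic ODEs, and executes a fixed seven-stage simulation loop with
    synaptic delays, refractoriness, short-term and spike-timing-dependent
    plasticity, recording monitors, stop conditions and structural plasticity.
    Hybrid networks couple the two frameworks through Poisson encoders and
    sliding-window spike-count decoders; weight-sharing projections provide
    convolution and pooling. Ships the standard PyNN-named neuron models, the
    classical rate-coded learning rules, and three reference networks
    (pulse-coupled Izhikevich, conductance-based integrate-and-fire benchmark,
    hybrid encode/decode demo).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
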