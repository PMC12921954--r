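Package: spikeye
Title: Saccade and Fixation Classification from Event-Camera Streams with
    Spiking Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for classifying eye movements (saccades versus
    fixations) recorded with neuromorphic event cameras. Provides an
    event-stream data model with CSV and Arrow container I/O, a synthetic
    near-eye scene and contrast-threshold event-camera emulator for
    generating labelled fixation/saccade streams, binary spike-tensor
    encoding, current-based leaky integrate-and-fire (CUBA-LIF) neuron
    dynamics, a spiking convolutional classifier trained end-to-end with
    surrogate-gradient backpropagation through time under a spike-rate
    loss, temporal-resolution sweep harnesses, and synaptic-operation
    versus multiply-accumulate complexity accounting with energy
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    data.table,
    arrow,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
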