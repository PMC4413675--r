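Package: rollsim
Title: Behavioral Simulation of a Reconfigurable On-Line Learning Spiking
    Neuromorphic Processor
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A behavioral software model of a ROLLS-class mixed-signal
    neuromorphic processor: 256 adaptive exponential integrate-and-fire
    silicon neurons, a 256x256 array of bistable long-term plasticity
    synapses with calcium-gated stop-learning, a 256x256 array of
    programmable short-term plasticity synapses with short-term
    depression, shared per-row linear differential-pair-integrator
    (DPI) synapse filters, virtual (time-multiplexed) synapses, a
    synapse de-multiplexer, and symbolic address-event routing
    (direct, broadcast and recurrent activation modes).  Includes
    seeded Poisson and event-camera-style stimulus generators, a
    plain-text address-event file format, and re-creations of two
    system-level experiments on synthetic inputs: competing
    attractor working-memory networks and an event-driven
    two-layer classifier trained with a spike-based teacher signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
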