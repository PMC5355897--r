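Package: lifnet
Title: Leaky Integrate-and-Fire Neural Circuit Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, scriptable simulation of small neural circuits built
    from leaky (and adaptive) integrate-and-fire neurons coupled by
    current-based exponential synapses. Provides stimulators (DC and AC
    current sources, regular and Poisson spike generators, scheduled touch
    events, receptive-field visual encoders), sensors (voltmeters, spike
    detectors, Gaussian-window firing-rate meters), a versioned JSON network
    format, prebuilt reference circuit motifs (spike threshold, synaptic
    summation, touch-gated inhibition, feedback inhibition, direction
    selectivity via one-sided lateral inhibition), and a command-line entry
    point for running networks as batch experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
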