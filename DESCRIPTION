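Package: optoclamp
Title: Closed-Loop Optogenetic Firing-Rate Control Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates continuous, bidirectional optogenetic feedback control
    of neuronal firing rate (the "optoclamp"). Provides the exponential
    firing-rate estimator, proportional-integral, pure-integral, and on-off
    (bang-bang) controllers with anti-windup, mappings from control variables
    to blue/yellow optical stimuli (pulse trains, triangle, sine, PRBS, and
    continuous waveforms), doubly-stochastic adapting spiking-plant models of
    a cultured cortical network and of a single thalamocortical unit, a
    multi-rate closed-loop engine with open-loop replay, control locking, and
    parameter sweeps, and a suite of spike-train metrics (RMS tracking error,
    settling time, cross-correlogram, synchrony index, CV of interspike
    intervals, spike-triggered average, FWHM, burst profiles).
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
    jsonlite
Config/testthat/edition: 3
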