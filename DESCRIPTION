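Package: gazedecode
Title: Linear Population Decoding of Time-Lagged Eye-Position Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates saccade-aligned spiking activity of cortical
    populations with eye-position gain fields and peri-saccadic transients,
    and decodes continuous, time-lagged eye-position signals from that
    activity with a fixed-weight linear read-out ("uber-neuron") estimated
    by cross-validated ridge regression. Includes firing-rate binning,
    principal-component summaries of direction-specific population
    dynamics, cumulative-Gaussian latency fits that quantify the achieved
    lag and represented saccade duration of the decoded signal, and
    analyses of how the pooling weights are distributed across neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
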