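Package: recordnet
Title: Extreme-Value Prediction and Correlation Networks for Annual Sports Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of annual world-record
    performances across sports events. Implements a Gaussian extreme-value
    prediction model for the expected record over N years with an
    uncertainty band (a quadratic polynomial in log log N calibrated
    against the exact distribution of the maximum of N iid Gaussians),
    span-wise record-evolution statistics, a relative-fluctuation
    transform that renders timed and distance events comparable, and
    thresholded Pearson correlation networks linking co-evolving events.
    Includes an exact order-statistic oracle, a seeded synthetic panel
    generator with planted drift and cross-event correlation, and an
    end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
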