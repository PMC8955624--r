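Package: stigmar
Title: Online Activity Recognition from Streaming Ambient Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Online recognition of activities of daily living from streaming
    binary ambient-sensor events (motion and door sensors in a smart home).
    Implements spatio-temporal dynamic segmentation of the event stream using
    windowed mutual-information sensor correlations with per-sensor
    correlation thresholds and "2 sigma" time-interval and time-span gates,
    and marker-based stigmergic activity modelling in which sensor
    activations deposit exponentially volatilizing pheromone on the edges of
    a directed weighted network. Includes fixed-size and time-interval
    windowing baselines, activation-duration feature vectors, a pluggable
    per-event classifier with a multinomial-logistic reference
    implementation, contiguous-block cross-validation, weighted
    precision/recall/F1 evaluation, a reader and writer for CASAS-style
    annotated event logs, and a seeded smart-home stream simulator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
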