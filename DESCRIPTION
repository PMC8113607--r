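Package: shiscale
Title: Sensory History Integration Scaling Across Stimulus Presentation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how neural integration of auditory sensory history
    scales with stimulus presentation rate. Generates naturalistic tone
    sequences with 1/f^beta pitch statistics by circulant embedding, computes
    the optimal linear prediction of the final tone pitch from a Toeplitz
    autocovariance system, simulates multi-sensor recordings and behavioral
    ratings with planted ground truth, estimates the number of integrated
    tones (k') per sensor and time window by six-fold cross-validated
    regression order selection with tone-order shuffle nulls, compares k'
    across presentation-rate conditions against duration- and
    information-bottleneck orientation lines (vector norm, angle, planar
    projection), and provides cluster-based permutation inference over sensor
    graphs and time, plus behavioral ANOVA and brain-behavior correlation
    analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    igraph,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
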