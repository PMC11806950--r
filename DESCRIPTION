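Package: infotrail
Title: Tracing Influence Paths with Tri-Variate Information and Widest Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies influence paths from a designated anchor feature
    through a multivariate dataset. Candidate links are scored with
    tri-variate interaction information gated by strict data-processing
    inequality conditions, and paths are extracted as widest (maxi-min)
    paths over a graph of ordered feature pairs using a bottleneck variant
    of Dijkstra's algorithm. Supports plug-in maximum-likelihood estimation
    on categorical data and the Kendall transformation for ordinal data,
    a permutation null model for score calibration, synthetic benchmark
    generators, and DOT/JSON/TSV exporters for the resulting influence trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
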