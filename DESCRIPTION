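Package: grnforge
Title: Simulation of Large Signed Gene Regulatory Networks and Supervised Edge Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast simulation of large signed transcriptional regulatory networks
    with scale-free degree behaviour, spectral conditioning of the linear
    expression dynamics (spectral-radius standardization and lifting of
    conjugate eigenvalue pairs onto the unit circle to obtain stable or
    stably oscillating transcriptomes), and generation of log-normal
    expression data with measurement noise. Includes a supervised
    edge-learning pipeline: prior-knowledge masks over the network
    (row/target-oriented or column/regulator-oriented, with controlled error
    injection), class-rebalanced training of a radial-basis-kernel support
    vector machine edge classifier, and benchmarking of reconstruction
    accuracy by signed true-positive and false-positive percentages with
    volume-under-surface summaries over (number of experiments x prior
    fraction) grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    kernlab,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
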