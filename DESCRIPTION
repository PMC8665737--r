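Package: nanocallr
Title: Nanopore Base Calling with Factorized Convolutions, CTC Decoding and
    a Squiggle Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale nanopore base caller built from first principles:
    1-D convolution factorizations (full, depthwise, pointwise, separable and
    k-blueprint-separable), residual blocks with depth-to-space compression,
    identity initialization, a CNN that maps raw current signal to per-frame
    posteriors over {A, C, G, T, blank}, CTC loss with exact gradients and
    greedy/beam decoding, and a synthetic squiggle simulator providing
    ground-truth sequences and event boundaries so the whole pipeline can be
    trained and evaluated on a single CPU. Includes a command-line interface
    for simulation, training, base calling and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
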