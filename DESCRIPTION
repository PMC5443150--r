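Package: spade
Title: Spatio-Temporal Spike Pattern Detection and Evaluation in Massively
    Parallel Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines closed, frequent, millisecond-precise spatio-temporal spike
    patterns (STPs) from massively parallel spike train recordings and separates
    genuine patterns from chance ones. Spike trains are discretized, chopped
    into sliding windows and re-encoded as a formal context whose concepts
    (closed frequent itemsets) are enumerated with a native LCM-style miner
    backed by a brute-force oracle. Candidate patterns are then filtered either
    by intensional/extensional concept stability (exact or Monte-Carlo
    approximated, with surrogate-derived thresholds) or by surrogate-based
    significance testing: pattern spectrum filtering (PSF) with false discovery
    rate correction followed by pattern set reduction (PSR). Includes stochastic
    generators for Poisson backgrounds with stationary and non-stationary rate
    models, ground-truth pattern injection, and a validation harness computing
    false-positive/false-negative matrices over pattern signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
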