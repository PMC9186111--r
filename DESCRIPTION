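Package: spikesurr
Title: Surrogate Generation and Significance Evaluation for Parallel Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating surrogate parallel spike trains (uniform
    dithering, uniform dithering with dead-time, joint-ISI dithering, ISI
    dithering, trial shifting, window shuffling), for simulating stationary and
    nonstationary renewal point processes (Poisson, Poisson with dead-time,
    Gamma) as null models, for quantifying how each surrogate distorts
    single-train statistics (interval distributions, correlograms, regularity,
    moved-spike ratio, spike-count loss under binarization), and for assessing
    the significance of repeating spatiotemporal spike patterns with a
    surrogate-based pattern-spectrum test with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
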