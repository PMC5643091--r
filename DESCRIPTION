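Package: deepcalseq
Title: Depth Profiling and Trial-Aligned Sequence Statistics for Deep
    Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies image quality as a function of depth in two-photon
    microscopy volumes (brightest-fraction signal, circular-Hough soma
    counting, intensity-profile FWHM, underfilled-objective optics) and
    analyses trial-aligned calcium traces from periodic-reward conditioning
    sessions: percentile-baseline dF/F detrending, lick-gated trial
    alignment, ridge-to-background sequence statistics against
    circular-shift nulls, split-half peak-time stability with resampled
    confidence intervals, cross-area permutation tests, and behavioural
    metrics (lick PSTH, response rate, reaction time).  Seeded
    synthetic-data generators provide full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
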