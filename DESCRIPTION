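Package: rtfluency
Title: Distributional Response-Time and Recognition-Memory Analysis for
    Perceptual Disfluency Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localising perceptual disfluency effects in word
    recognition: ex-Gaussian decomposition of encoding response times with
    identity/log link contrast coding, four-parameter Wiener diffusion
    first-passage densities and fitting, Vincentile quantile and delta-plot
    profiling with qualitative pattern classification, and equal-variance
    signal detection analysis of old/new recognition via probit regression.
    Includes a synthetic-experiment generator that emulates counterbalanced
    blur-by-frequency designs with known ground truth, plus bootstrap
    credible-interval, posterior-probability and evidence-ratio summaries
    with the directional hypothesis decision rule.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
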