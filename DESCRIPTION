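Package: anloud
Title: Auditory-Nerve Based Loudness Modelling and Hyperacusis Gain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the auditory periphery (outer/middle-ear filtering, a
    dual-resonance non-linear cochlear filterbank with human parameters, and a
    simplified leaky-integrate-and-fire auditory-nerve population with three
    spontaneous-rate classes), computes loudness in sones from summed
    auditory-nerve activity, derives equal-loudness contours by matched-activity
    search, and fits central gain mechanisms (linear or power-law, sub- or
    supra-threshold, frequency-dependent or -independent) to audiometric
    loudness-discomfort data, for the study of abnormal loudness perception
    in hyperacusis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
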