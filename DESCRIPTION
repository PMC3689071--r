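Package: cdfd
Title: Spike-Train and Behavioral Analysis for Context-Dependent Fear
    Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing prefrontal single-unit recordings and
    behavior from context-dependent fear discrimination experiments, in
    which the same tone conditioned stimulus predicts shock in one context
    but not another. Provides trial-aligned peristimulus time histograms,
    baseline Z-score normalization at 50-ms and 1-s resolutions, 3-SD
    responsive-unit classification (short-latency and persistently firing
    units), per-unit context-modulation t-values over matched bins, a
    direction chi-square, paired window tests, a two-within-factor
    repeated-measures ANOVA for habituation analyses, freezing and
    prepulse-inhibition metrics, and an inhomogeneous-Poisson synthetic
    data generator that emulates the recording experiment so the full
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
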