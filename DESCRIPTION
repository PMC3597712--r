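Package: dynstates
Title: Dynamical Non-Stationarity Analysis of Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies dynamical non-stationarity of resting-state EEG by
    segmenting each channel into half-overlapping windows, fitting a
    polynomial map to every window by least squares, clustering windows in
    model-coefficient space with a two-stage affinity-propagation scheme,
    and summarising each epoch by the number of quasi-stationary states and
    the mean duration of glued quasi-stationary segments. Group and
    condition effects on these measures are assessed with mean-centered and
    contrast partial least squares (permutation tests and bootstrap
    ratios), and their spectral correlates with partial correlations
    against relative band power. A regime-switching signal generator
    produces piecewise-stationary synthetic cohorts with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
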