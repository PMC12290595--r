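Package: connstream
Title: Online Functional Connectivity Estimation for Streaming Multichannel Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An online (incremental, trial-by-trial) functional connectivity engine
    for streaming multichannel electrophysiological data. Implements nine
    across-trial connectivity estimators (correlation, cross-correlation,
    coherency, coherence, imaginary coherency, phase-locking value, phase-lag
    index and its unbiased/weighted/debiased variants) on top of a shared
    cross-spectral accumulator, together with a streaming front end
    (linear-phase FIR filtering with overlap-add, trigger-based epoching,
    baseline correction, artifact rejection, running covariance, linear
    source-operator application), all-to-all network containers with
    normalization, top-fraction thresholding and graph measures, and a
    two-source sinusoid simulator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    yaml
Config/testthat/edition: 3
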