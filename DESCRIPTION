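Package: abtrf
Title: Amplitude-Binned Temporal Response Functions for Continuous EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward (encoding) modelling of EEG responses to continuous
    amplitude-modulated sound with temporal response functions (TRFs).
    Implements the amplitude-binned envelope representation, in which the
    acoustic envelope is split into logarithmically spaced amplitude bins so
    that the fitted multivariate TRF can change magnitude, latency and
    morphology with stimulus intensity, together with the competing univariate
    representations (envelope, SPL envelope, onset/offset/derivative
    envelopes), ridge-regularised lagged-design estimation, nested
    leave-one-out cross-validation with per-trial model averaging,
    circular-shift and shuffle permutation nulls, channel selection,
    paired model comparisons (t, Cohen's d, Wilcoxon, AIC), P1/N1 peak-latency
    analyses across amplitude bins, and a synthetic stimulus/EEG generator
    with known amplitude-dependent response structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    nortest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
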