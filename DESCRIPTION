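Package: aecren
Title: Renormalized Amplitude Envelope Correlation for Electrophysiological Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spectrally resolved amplitude envelope correlation (AEC) between
    narrow-band neural signals is systematically underestimated when the
    signal-to-noise ratio is low (the "power bias"). aecren implements a
    renormalization of AEC estimates that corrects this bias using
    second-order statistics of a background-noise model, together with the
    supporting machinery: a narrow-band Hilbert filterbank with zero-lag
    leakage orthogonalization, a two-state gaussian hidden Markov model that
    separates bursting from non-bursting oscillatory activity and estimates
    noise statistics from coincident non-bursting periods, a synthetic-signal
    simulator with controlled envelope coupling and SNR for validation
    experiments, and spectral-similarity tests with effective spectral
    degrees of freedom and family-wise error control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
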