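Package: ampbalance
Title: Timescale-Aligned Amplitude Balance Analysis for Multichannel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies amplitude disparity between temporally misaligned
    signals using a gamma-parameterized, window-constrained dynamic time
    warping (DTW) metric, its path-length-normalized variant (nDTW), and a
    shape-preserving time-resolved disparity trace. Includes band-pass
    preparation of BOLD-like network time courses with a cutoff-derived
    warping-window rule, phase-randomization surrogate null models
    (full-band and band-residual), test-retest reliability statistics,
    k-means extraction of recurring convergence/divergence states with
    city-block distance, and Markov-chain analytics of state dynamics
    (stationary distribution, spectral gap, total-variation mixing time,
    entropy rate, dwell time, occupancy, and transition perturbation
    analysis). Ships synthetic-data generators emulating band-limited
    network time courses with controllable amplitude/phase modulation and
    planted state schedules so the full pipeline is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
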