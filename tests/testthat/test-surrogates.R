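test_that("phase randomization preserves spectra and correlations", {
  for (nt in c(96, 97)) {                 # even and odd lengths
    p <- make_panel(2, 4, nt, seed = 31)
    s <- phase_randomize(p, seed = 7)
    for (su in 1:2) for (ch in 1:4) {
      A0 <- Mod(stats::fft(p$data[su, ch, ]))
      A1 <- Mod(stats::fft(s$data[su, ch, ]))
      expect_lt(max(abs(A1 - A0)) / max(A0), 1e-10)
    }
    for (su in 1:2) {
      C0 <- stats::cor(t(p$data[su, , ]))
      C1 <- stats::cor(t(s$data[su, , ]))
      expect_lt(max(abs(C1 - C0)), 1e-10)
      # circular autocorrelation preserved (Wiener-Khinchin)
      cacf <- function(v) Re(stats::fft(Mod(stats::fft(v))^2,
                                        inverse = TRUE)) / length(v)
      expect_lt(max(abs(cacf(s$data[su, 1, ]) - cacf(p$data[su, 1, ]))) /
                  cacf(p$data[su, 1, ])[1], 1e-10)
    }
    # the surrogate is a genuinely different series
    expect_gt(max(abs(s$data - p$data)), 0.1)
  }
})

test_that("phase randomization is deterministic under its seed", {
  p <- make_panel(1, 3, 64, seed = 5)
  expect_identical(phase_randomize(p, seed = 3)$data,
                   phase_randomize(p, seed = 3)$data)
  expect_false(identical(phase_randomize(p, seed = 3)$data,
                         phase_randomize(p, seed = 4)$data))
})

test_that("independent-phase mode destroys cross-channel correlation", {
  p <- make_panel(1, 2, 400, seed = 44)
  # make the two channels strongly correlated
  p$data[1, 2, ] <- 0.9 * p$data[1, 1, ] + 0.1 * p$data[1, 2, ]
  r0 <- stats::cor(p$data[1, 1, ], p$data[1, 2, ])
  s <- phase_randomize(p, seed = 2, shared = FALSE)
  r1 <- stats::cor(s$data[1, 1, ], s$data[1, 2, ])
  expect_gt(abs(r0), 0.9)
  expect_lt(abs(r1), abs(r0) - 0.3)
})

test_that("band-residual surrogates preserve the low band and the seed contract", {
  tr <- 2; nt <- 300
  f1 <- design_bandpass(0.01, 0.198, tr)
  f2 <- design_bandpass(0.01, 0.15, tr)
  raw <- make_panel(1, 3, nt, seed = 17)
  p1 <- apply_zero_phase(raw, f1)
  p2 <- apply_zero_phase(p1, f2)
  spec <- surrogate_spec(n_surrogates = 2, seed = 9)
  surr <- band_residual_surrogate(p1, f2, spec, panel_f2 = p2)
  expect_length(surr, 2)
  freqs <- (seq_len(nt) - 1) / nt / tr
  freqs <- pmin(freqs, 1 / tr - freqs)
  low <- freqs >= 0.01 & freqs <= 0.13    # clear of the transition edge
  for (ch in 1:3) {
    X2 <- stats::fft(p2$data[1, ch, ])
    XS <- stats::fft(surr[[1]]$data[1, ch, ])
    rel <- sum(Mod(XS - X2)[low]^2) / sum(Mod(X2)[low]^2)
    expect_lt(rel, 1e-2)
    # residual band content differs (it was randomized)
    hi <- freqs >= 0.16 & freqs <= 0.198
    expect_gt(sum(Mod(XS - X2)[hi]^2) / sum(Mod(X2)[hi]^2 + 1e-12), 0.05)
  }
  surr_b <- band_residual_surrogate(p1, f2, spec, panel_f2 = p2)
  expect_identical(surr[[1]]$data, surr_b[[1]]$data)
  expect_false(identical(surr[[1]]$data, surr[[2]]$data))
})

test_that("an already narrow-band panel yields a near-identity surrogate", {
  tr <- 2
  f2 <- design_bandpass(0.01, 0.15, tr)
  raw <- make_panel(1, 2, 300, seed = 23)
  p2 <- apply_zero_phase(raw, f2)         # input has no residual band content
  surr <- band_residual_surrogate(p2, f2, surrogate_spec(1, seed = 3),
                                  panel_f2 = p2)[[1]]
  rel <- sqrt(sum((surr$data - p2$data)^2) / sum(p2$data^2))
  # the residual X is not exactly zero: content near the 0.15 Hz band edge
  # sits where the filter attenuates only partially (-3 dB at the edge,
  # |H|^2(1 - |H|^2) leakage across the transition band), so "identity"
  # holds to the filter's transition-band tolerance of ~10-15% in RMS
  expect_lt(rel, 0.15)
})

test_that("mismatched panels are rejected", {
  f2 <- design_bandpass(0.01, 0.15, 2)
  p1 <- make_panel(1, 2, 100, seed = 1)
  p2 <- make_panel(1, 2, 90, seed = 2)
  expect_error(band_residual_surrogate(p1, f2, surrogate_spec(1, 1), p2),
               "mismatched")
})

test_that("surrogate null test calibrates and adjusts", {
  set.seed(99)
  # single observed value per pair: empirical rank p is uniform under the null
  n_surr <- 99
  hits <- replicate(400, {
    surr <- matrix(rnorm(n_surr), ncol = 1)
    obs <- rnorm(1)
    surrogate_null_test(obs, surr, alternative = "greater")$p <= 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
  # observed far above all surrogates: minimal attainable p
  surr <- matrix(rnorm(200 * 3), 200, 3)
  res <- surrogate_null_test(c(50, 50, 50), surr, alternative = "greater")
  expect_equal(res$p, rep(1 / 201, 3))
  # single pair: BH adjustment is the identity
  r1 <- surrogate_null_test(0.2, matrix(rnorm(50), ncol = 1))
  expect_equal(r1$p_adj, r1$p)
  # multi-observation mode uses the rank-sum test
  obs <- matrix(rnorm(30, mean = 2), ncol = 1)
  r2 <- surrogate_null_test(obs, matrix(rnorm(100), ncol = 1),
                            alternative = "greater")
  expect_lt(r2$p, 1e-6)
})
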