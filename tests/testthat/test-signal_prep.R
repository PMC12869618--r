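test_that("band-pass design meets the ripple/attenuation contract", {
  for (band in list(c(0.01, 0.15), c(0.01, 0.198))) {
    spec <- design_bandpass(band[1], band[2], tr = 2)
    # half-power points sit at the band edges: 10*log10(2) = 3.0103 dB
    pass_db <- 20 * log10(filter_response(spec, band))
    expect_true(all(pass_db >= -3.02))
    stop_db <- 20 * log10(filter_response(spec, c(spec$stop_lo, spec$stop_hi)))
    expect_true(all(stop_db <= -30))
    # interior of the passband is flatter than the edges (maximally flat)
    mid_db <- 20 * log10(filter_response(spec, mean(band)))
    expect_gt(mid_db, -0.5)
    expect_gte(spec$order, 1)
  }
})

test_that("band-pass spec serializes losslessly", {
  spec <- design_bandpass(0.01, 0.15, tr = 2)
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  rebuilt <- design_bandpass(back$f_lo, back$f_hi, back$tr,
                             stop_margins = c(back$stop_lo, back$stop_hi))
  expect_equal(rebuilt$order, spec$order)
  expect_equal(rebuilt$b, spec$b)
  expect_equal(rebuilt$a, spec$a)
})

test_that("bands outside Nyquist are rejected", {
  expect_error(design_bandpass(0.01, 0.30, tr = 2), "invalid band")
  expect_error(design_bandpass(0, 0.1, tr = 2), "invalid band")
  expect_silent(design_bandpass(0.01, 0.198, tr = 2))  # f_hi < 0.25 feasible
})

test_that("zero-phase filtering passes in-band content without lag", {
  tr <- 2
  t <- (0:299) * tr
  spec <- design_bandpass(0.01, 0.15, tr = tr)
  x <- sin(2 * pi * 0.05 * t)
  p <- ts_panel(array(x, c(1, 1, length(x))), tr = tr)
  y <- apply_zero_phase(p, spec)$data[1, 1, ]
  mid <- 120:180
  # amplitude preserved within 5% mid-series
  expect_lt(abs(max(abs(y[mid])) - max(abs(x[mid]))), 0.05)
  # no phase shift: cross-correlation peaks at lag 0
  cc <- stats::ccf(y[mid], x[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("zero-phase filtering attenuates out-of-band content", {
  tr <- 2
  t <- (0:299) * tr
  spec <- design_bandpass(0.01, 0.15, tr = tr)
  x <- sin(2 * pi * 0.22 * t)
  p <- ts_panel(array(x, c(1, 1, length(x))), tr = tr)
  y <- apply_zero_phase(p, spec)$data[1, 1, ]
  # >= 30 dB down mid-series (forward-backward doubles the attenuation)
  expect_lt(max(abs(y[120:180])), 10^(-30 / 20))
  # linearity: zero in, zero out
  out0 <- apply_zero_phase(ts_panel(array(0, c(1, 1, 300)), tr = tr), spec)
  expect_equal(max(abs(out0$data)), 0)
})

test_that("filtering refuses series shorter than the warm-up length", {
  spec <- design_bandpass(0.01, 0.15, tr = 2)
  p <- ts_panel(array(rnorm(10), c(1, 1, 10)), tr = 2)
  expect_error(apply_zero_phase(p, spec), "too short")
})

test_that("z-scoring standardizes, is idempotent and affine-invariant", {
  p <- make_panel(2, 3, 100, seed = 4)
  z <- zscore_panel(p)
  for (s in 1:2) for (ch in 1:3) {
    expect_lt(abs(mean(z$data[s, ch, ])), 1e-12)
    expect_lt(abs(stats::sd(z$data[s, ch, ]) - 1), 1e-12)
  }
  expect_equal(zscore_panel(z)$data, z$data, tolerance = 1e-12)
  shifted <- ts_panel(3.2 * p$data + 7, tr = p$tr)
  expect_equal(zscore_panel(shifted)$data, z$data, tolerance = 1e-10)
})

test_that("z-scoring names the degenerate channel", {
  a <- array(rnorm(2 * 2 * 30), c(2, 2, 30))
  a[2, 1, ] <- 5
  p <- ts_panel(a, tr = 2, channel_labels = c("DMN", "CER"),
                subject_ids = c("s1", "s2"))
  expect_error(zscore_panel(p), "s2.*DMN")
})

test_that("window rule reproduces the cutoff arithmetic", {
  w <- dtw_window_from_cutoff(0.01, 2)
  expect_equal(as.integer(w), 45L)
  expect_equal(attr(w, "N"), 90)
  w2 <- dtw_window_from_cutoff(0.01, 1)
  expect_equal(as.integer(w2), 89L)
  expect_equal(attr(w2, "N"), 178)
})

test_that("window rule is monotone and clamps at degenerate cutoffs", {
  f <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  ws <- sapply(f, function(fi) as.integer(dtw_window_from_cutoff(fi, 2)))
  expect_true(all(diff(ws) < 0))
  trs <- c(0.5, 1, 2, 3)
  wt <- sapply(trs, function(tri) as.integer(dtw_window_from_cutoff(0.01, tri)))
  expect_true(all(diff(wt) < 0))
  expect_warning(wbig <- dtw_window_from_cutoff(1e6, 2), "clamped")
  expect_equal(as.integer(wbig), 1L)
})

test_that("ideal-filter reasoning: 100 s wavelength, 50 s shift at 0.01 Hz", {
  r <- window_rationale(0.01, tr = 2)
  expect_identical(r$wavelength_s, 100)
  expect_identical(r$half_shift_s, 50)
  expect_identical(r$ideal_window_s, 100)
  expect_identical(r$ideal_window_samples, 50)
  # the cutoff-rule window is at least as long as the ideal-filter bound
  expect_gte(attr(dtw_window_from_cutoff(0.01, 2), "N"), 50)
})
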