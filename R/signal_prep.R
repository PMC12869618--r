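#' Design a minimum-order Butterworth band-pass filter
#'
#' Finds the lowest-order Butterworth band-pass whose magnitude response has
#' no more than `passband_ripple_db` attenuation inside `[f_lo, f_hi]` and at
#' least `stopband_atten_db` attenuation at the stop edges. The order is
#' obtained from the analog-prototype order formula after bilinear
#' pre-warping (the same computation MATLAB's `buttord` performs); the
#' natural frequencies are the passband edges, so the half-power (-3 dB)
#' points of the design sit exactly at `f_lo` and `f_hi`.
#'
#' Stop edges default to `f_lo / 2` and `min(f_hi + 0.05, 0.98 * Nyquist)`;
#' they are recorded in the returned spec so a design is fully reproducible
#' from its serialized form.
#'
#' @param f_lo,f_hi passband edges in Hz.
#' @param tr sampling interval in seconds.
#' @param stop_margins optional numeric pair `c(stop_lo, stop_hi)` in Hz
#'   overriding the default stop edges.
#' @param passband_ripple_db,stopband_atten_db design contract in dB.
#' @return A `bandpass_spec` object: band edges, stop edges, filter order
#'   `order` (order of the low-pass prototype; the band-pass has `2 * order`
#'   poles), and the digital filter coefficients `b`, `a`.
#' @examples
#' spec <- design_bandpass(0.01, 0.15, tr = 2)
#' spec$order
#' @export
design_bandpass <- function(f_lo, f_hi, tr,
                            stop_margins = NULL,
                            passband_ripple_db = 3,
                            stopband_atten_db = 30) {
  nyq <- 1 / (2 * tr)
  if (!(0 < f_lo && f_lo < f_hi && f_hi < nyq))
    stop(sprintf("invalid band: need 0 < f_lo < f_hi < Nyquist = %g Hz", nyq))
  if (is.null(stop_margins))
    stop_margins <- c(f_lo / 2, min(f_hi + 0.05, 0.98 * nyq))
  stop_lo <- stop_margins[1]; stop_hi <- stop_margins[2]
  if (!(0 < stop_lo && stop_lo < f_lo && f_hi < stop_hi && stop_hi <= nyq))
    stop("stop edges must satisfy 0 < stop_lo < f_lo < f_hi < stop_hi <= Nyquist")

  ## analog prototype order after bilinear pre-warping
  warp <- function(f) tan(pi * f * tr)       # f / nyq * pi / 2 * 2
  wp <- warp(c(f_lo, f_hi)); ws <- warp(c(stop_lo, stop_hi))
  bw <- wp[2] - wp[1]; w0sq <- wp[1] * wp[2]
  wa <- min(abs((ws^2 - w0sq) / (ws * bw)))  # tighter of the two stop edges
  Rp <- passband_ripple_db; Rs <- stopband_atten_db
  order <- ceiling(log10((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1)) /
                     (2 * log10(wa)))
  order <- max(1L, as.integer(order))

  bt <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  structure(
    list(f_lo = f_lo, f_hi = f_hi, tr = tr,
         stop_lo = stop_lo, stop_hi = stop_hi,
         passband_ripple_db = Rp, stopband_atten_db = Rs,
         order = order, family = "butterworth",
         b = as.numeric(bt$b), a = as.numeric(bt$a)),
    class = "bandpass_spec")
}

#' @export
print.bandpass_spec <- function(x, ...) {
  cat(sprintf(
    "bandpass_spec: %s order %d, pass %.4g-%.4g Hz, stop %.4g/%.4g Hz (Rp %g dB, Rs %g dB), TR %g s\n",
    x$family, x$order, x$f_lo, x$f_hi, x$stop_lo, x$stop_hi,
    x$passband_ripple_db, x$stopband_atten_db, x$tr))
  invisible(x)
}

#' Magnitude response of a designed filter
#'
#' Evaluates `|H(e^{i 2 pi f tr})|` of the single-pass filter on a frequency
#' grid; used to verify the design contract and for documentation plots.
#'
#' @param spec a [bandpass_spec][design_bandpass].
#' @param f frequencies in Hz.
#' @return numeric vector of magnitudes (linear scale; square for the
#'   zero-phase forward-backward application).
#' @export
filter_response <- function(spec, f) {
  w <- 2 * pi * f * spec$tr
  vapply(w, function(wi) {
    zb <- exp(-1i * wi * (seq_along(spec$b) - 1))
    za <- exp(-1i * wi * (seq_along(spec$a) - 1))
    Mod(sum(spec$b * zb) / sum(spec$a * za))
  }, numeric(1))
}

#' Zero-phase band-pass filtering of a panel
#'
#' Applies the filter forward and backward (`signal::filtfilt`) to every
#' channel of every subject, which squares the magnitude response and
#' cancels the phase response, so in-band content is passed without lag.
#' Edge transients are not trimmed here; trimming happens once, before
#' state clustering.
#'
#' @param panel a [ts_panel].
#' @param spec a [bandpass_spec][design_bandpass] with the same TR.
#' @return A filtered [ts_panel] with updated band metadata.
#' @export
apply_zero_phase <- function(panel, spec) {
  stopifnot(inherits(panel, "ts_panel"), inherits(spec, "bandpass_spec"))
  if (abs(panel$tr - spec$tr) > 1e-12)
    stop("panel TR and filter TR differ")
  nt <- n_timepoints(panel)
  warmup <- 3 * max(length(spec$b), length(spec$a))
  if (nt <= warmup)
    stop(sprintf("series too short for the filter: %d timepoints <= warm-up length %d",
                 nt, warmup))
  filt <- signal::Arma(b = spec$b, a = spec$a)
  out <- panel$data
  for (s in seq_len(n_subjects(panel)))
    for (ch in seq_len(n_channels(panel)))
      out[s, ch, ] <- signal::filtfilt(filt, panel$data[s, ch, ])
  ts_panel(out, tr = panel$tr, band = c(spec$f_lo, spec$f_hi),
           channel_labels = panel$channel_labels,
           subject_ids = panel$subject_ids)
}

#' Per-channel z-scoring
#'
#' Standardizes each subject's each channel to mean 0 and (sample) standard
#' deviation 1 over time. Idempotent; errors on zero-variance channels.
#'
#' @param panel a [ts_panel].
#' @return A z-scored [ts_panel].
#' @export
zscore_panel <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  out <- panel$data
  for (s in seq_len(n_subjects(panel)))
    for (ch in seq_len(n_channels(panel))) {
      v <- panel$data[s, ch, ]
      sdv <- stats::sd(v)
      if (!is.finite(sdv) || sdv == 0)
        stop(sprintf("degenerate (zero-variance) channel: subject '%s', channel '%s'",
                     panel$subject_ids[s], panel$channel_labels[ch]))
      out[s, ch, ] <- (v - mean(v)) / sdv
    }
  ts_panel(out, tr = panel$tr, band = panel$band,
           channel_labels = panel$channel_labels,
           subject_ids = panel$subject_ids)
}

#' Warping-window half-width from the filter's low-frequency cutoff
#'
#' Ties the DTW window constraint to the spectral content of the prepared
#' signal: the -3 dB low cutoff `f3db` determines the longest period present,
#' and the window must be wide enough to capture lead/lag deformations up to
#' the half-period that produces full anti-correlation. The adopted rule is
#'
#'   `f3db = 0.88 / ((N/2 - 1) * tr)`,  solved as  `N = 2 * (0.88 / (f3db * tr) + 1)`,
#'
#' where `N` is the total window length in samples; the returned one-sided
#' Sakoe-Chiba half-width is `w = round(N / 2)`, constraining `|i - j| <= w`.
#' For `f3db = 0.01` Hz and TR = 2 s this gives `N = 90` samples (180 s),
#' comfortably above the 100 s (50-sample) ideal-filter lower bound derived
#' in [window_rationale()].
#'
#' @param f3db low-frequency -3 dB cutoff in Hz.
#' @param tr sampling interval in seconds.
#' @return Integer half-width `w >= 1` (attribute `N` carries the full
#'   window length in samples).
#' @examples
#' dtw_window_from_cutoff(0.01, 2)   # 45
#' @export
dtw_window_from_cutoff <- function(f3db, tr) {
  stopifnot(f3db > 0, tr > 0)
  nyq <- 1 / (2 * tr)
  if (f3db >= nyq)
    warning("f3db at or above Nyquist; window clamped to 1")
  N <- 2 * (0.88 / (f3db * tr) + 1)
  w <- max(1L, as.integer(round(N / 2)))
  structure(w, N = round(N))
}

#' Ideal-filter window reasoning at a low cutoff
#'
#' Documentation path for the window rule: with an ideal filter, the longest
#' wavelength at low cutoff `f3db` is `1 / f3db` seconds; producing an
#' anti-correlation of -1 requires a shift of half that wavelength; two such
#' half-wavelength windows (one per direction) give the total ideal window.
#' At 0.01 Hz this is a 100 s wavelength, a 50 s shift, and a 100 s window.
#'
#' @param f3db low cutoff in Hz.
#' @param tr optional sampling interval to also report sample counts.
#' @return list with `wavelength_s`, `half_shift_s`, `ideal_window_s` and,
#'   when `tr` is given, `ideal_window_samples`.
#' @export
window_rationale <- function(f3db, tr = NULL) {
  stopifnot(f3db > 0)
  out <- list(wavelength_s = 1 / f3db,
              half_shift_s = 1 / (2 * f3db),
              ideal_window_s = 1 / f3db)
  if (!is.null(tr)) out$ideal_window_samples <- (1 / f3db) / tr
  out
}
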