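#' Multivariate phase randomization
#'
#' Draws one random phase sequence per subject and adds it to the spectra of
#' *all* channels identically before inverting the FFT. Adding a common
#' phase leaves every cross-spectrum (hence the full linear correlation and
#' autocorrelation structure) and every per-channel amplitude spectrum
#' untouched to machine precision; only phase-dependent (non-stationary,
#' higher-order) structure is destroyed. The DC and Nyquist bins receive
#' zero added phase and conjugate symmetry is enforced explicitly so the
#' output is exactly real.
#'
#' @param panel a [ts_panel].
#' @param seed integer seed; every random draw is routed through it.
#' @param shared if `FALSE`, each channel gets its own phase sequence
#'   (diagnostic mode; correlations are then not preserved).
#' @return A surrogate [ts_panel] with the same metadata.
#' @export
phase_randomize <- function(panel, seed, shared = TRUE) {
  stopifnot(inherits(panel, "ts_panel"))
  nt <- n_timepoints(panel)
  half <- floor((nt - 1) / 2)              # positive non-Nyquist bins
  out <- panel$data
  set.seed(as.integer(seed))
  for (s in seq_len(n_subjects(panel))) {
    theta_shared <- stats::runif(half, 0, 2 * pi)
    for (ch in seq_len(n_channels(panel))) {
      theta <- if (shared) theta_shared else stats::runif(half, 0, 2 * pi)
      X <- stats::fft(panel$data[s, ch, ])
      rot <- rep(1 + 0i, nt)
      if (half > 0) {
        rot[2:(half + 1)] <- exp(1i * theta)
        rot[nt:(nt - half + 1)] <- Conj(rot[2:(half + 1)])
      }
      # DC (bin 1) and, for even nt, the Nyquist bin (nt/2 + 1) stay at 1
      out[s, ch, ] <- Re(stats::fft(X * rot, inverse = TRUE)) / nt
    }
  }
  ts_panel(out, tr = panel$tr, band = panel$band,
           channel_labels = panel$channel_labels,
           subject_ids = panel$subject_ids)
}

#' Surrogate generation specification
#'
#' @param n_surrogates number of independent surrogate panels.
#' @param seed integer; surrogate `k` uses `seed + k - 1`.
#' @param mode `"band_residual"` (randomize only the residual high band) or
#'   `"full_band"`.
#' @param residual_band,base_band informational band annotations (Hz) for
#'   the band-residual scheme.
#' @return A `surrogate_spec` object.
#' @export
surrogate_spec <- function(n_surrogates = 1000, seed = 1,
                           mode = c("band_residual", "full_band"),
                           residual_band = c(0.15, 0.198),
                           base_band = c(0.01, 0.15)) {
  mode <- match.arg(mode)
  stopifnot(n_surrogates >= 1)
  if (mode == "band_residual" && residual_band[1] < base_band[2])
    stop("residual band must lie above the base band's upper edge")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed), mode = mode,
                 residual_band = residual_band, base_band = base_band),
            class = "surrogate_spec")
}

#' Band-residual phase-randomization surrogates
#'
#' Builds surrogates whose randomization affects only the residual high
#' band (e.g. 0.15-0.198 Hz), in four steps per draw:
#' \enumerate{
#'   \item `Z` = phase-randomized copy of the wide-band (F1) panel;
#'   \item `Y` = `Z` filtered with the same band-pass used to obtain the
#'     original narrow-band (F2) data;
#'   \item `X = Z - Y`, the surrogate residual high-frequency content
#'     (a high-pass filter is *not* used, to avoid edge artifacts near the
#'     band boundary);
#'   \item surrogate `= X +` original F2 panel.
#' }
#' The 0.01-0.15 Hz content of each surrogate therefore equals the original
#' F2 data by construction, up to the filter's passband tolerance.
#'
#' @param panel_f1 wide-band (F1-filtered) [ts_panel].
#' @param bandpass_f2 the [bandpass_spec][design_bandpass] that produced the
#'   original F2 data.
#' @param spec a [surrogate_spec] (mode `"band_residual"`).
#' @param panel_f2 the original F2 panel; if `NULL`, derived by filtering
#'   `panel_f1` with `bandpass_f2`.
#' @return list of `n_surrogates` surrogate [ts_panel]s.
#' @export
band_residual_surrogate <- function(panel_f1, bandpass_f2, spec,
                                    panel_f2 = NULL) {
  stopifnot(inherits(panel_f1, "ts_panel"),
            inherits(bandpass_f2, "bandpass_spec"),
            inherits(spec, "surrogate_spec"))
  if (is.null(panel_f2))
    panel_f2 <- apply_zero_phase(panel_f1, bandpass_f2)
  if (!identical(dim(panel_f1$data), dim(panel_f2$data)))
    stop("F1 and F2 panels have mismatched dimensions")
  if (abs(panel_f1$tr - panel_f2$tr) > 1e-12)
    stop("F1 and F2 panels have mismatched TR")
  lapply(seq_len(spec$n_surrogates), function(k) {
    Z <- phase_randomize(panel_f1, seed = spec$seed + k - 1L)
    Y <- apply_zero_phase(Z, bandpass_f2)
    X <- Z$data - Y$data
    ts_panel(X + panel_f2$data, tr = panel_f1$tr, band = panel_f1$band,
             channel_labels = panel_f1$channel_labels,
             subject_ids = panel_f1$subject_ids)
  })
}

#' Surrogate null test per pair
#'
#' Rank-based comparison of observed pair statistics against their
#' surrogate null distributions, with Benjamini-Hochberg adjustment across
#' pairs. With several observed values per pair (e.g. one per subject) a
#' Wilcoxon rank-sum test is used; with a single observed value per pair
#' the empirical rank p-value `(1 + #{more extreme}) / (1 + n_surrogates)`
#' is returned.
#'
#' @param observed numeric vector (one statistic per pair) or matrix
#'   `[n_observed x n_pairs]`.
#' @param surrogate_stats matrix `[n_surrogates x n_pairs]`.
#' @param alternative `"two.sided"`, `"greater"` (observed above null) or
#'   `"less"`.
#' @return data.frame with columns `pair`, `p`, `p_adj`.
#' @export
surrogate_null_test <- function(observed, surrogate_stats,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.vector(observed)) observed <- matrix(observed, nrow = 1)
  stopifnot(ncol(observed) == ncol(surrogate_stats),
            nrow(surrogate_stats) >= 1)
  np <- ncol(observed)
  p <- vapply(seq_len(np), function(j) {
    obs <- observed[, j]; surr <- surrogate_stats[, j]
    if (length(obs) > 1) {
      stats::wilcox.test(obs, surr, alternative = alternative,
                         exact = FALSE)$p.value
    } else {
      n <- length(surr)
      p_hi <- (1 + sum(surr >= obs)) / (1 + n)
      p_lo <- (1 + sum(surr <= obs)) / (1 + n)
      switch(alternative,
             greater = p_hi, less = p_lo,
             two.sided = min(1, 2 * min(p_hi, p_lo)))
    }
  }, numeric(1))
  data.frame(pair = seq_len(np), p = p,
             p_adj = stats::p.adjust(p, method = "BH"))
}
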