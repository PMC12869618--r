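#' Amplitude/phase-modulated sinusoid pair
#'
#' Generates a base sinusoid `x` and a perturbed copy
#' `y = (1 + a m(t)) sin(2 pi f t + phi p(t))`, where `m` and `p` are slow
#' sinusoidal modulators at `mod_freq` with seeded random phases. With
#' `phase_mod_index = 0` the pair differs only in (time-varying) amplitude;
#' with `amp_mod_index = 0` only in phase -- the two axes of the
#' sensitivity simulations.
#'
#' @param base_freq carrier frequency in Hz.
#' @param amp_mod_index amplitude modulation index `a >= 0`.
#' @param phase_mod_index phase modulation index `phi >= 0` (radians).
#' @param mod_freq modulator frequency in Hz (slow relative to the carrier).
#' @param duration length in seconds.
#' @param fs sampling frequency in Hz (`> 2 base_freq`).
#' @param seed integer seed for the modulator phases.
#' @return list with `x`, `y`, `t`.
#' @export
gen_modulated_pair <- function(base_freq = 0.05, amp_mod_index = 0,
                               phase_mod_index = 0, mod_freq = 0.005,
                               duration = 600, fs = 0.5, seed = 1) {
  stopifnot(fs > 2 * base_freq, amp_mod_index >= 0, phase_mod_index >= 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  set.seed(as.integer(seed))
  psi <- stats::runif(2, 0, 2 * pi)
  m <- sin(2 * pi * mod_freq * t + psi[1])
  p <- sin(2 * pi * mod_freq * t + psi[2])
  x <- sin(2 * pi * base_freq * t)
  y <- (1 + amp_mod_index * m) * sin(2 * pi * base_freq * t + phase_mod_index * p)
  list(x = x, y = y, t = t)
}

#' Band-limited unit-variance Gaussian noise
#'
#' White Gaussian noise restricted (by spectral truncation) to
#' `[0, bandwidth_fraction * Nyquist]` and rescaled to zero mean and unit
#' variance. Larger fractions give faster, more irregular series.
#'
#' @param bandwidth_fraction fraction of Nyquist in (0, 1].
#' @param n series length.
#' @param fs sampling frequency in Hz.
#' @param seed integer seed.
#' @return numeric series of length `n`.
#' @export
gen_band_limited_noise <- function(bandwidth_fraction, n, fs = 0.5, seed = 1) {
  stopifnot(bandwidth_fraction > 0, bandwidth_fraction <= 1, n >= 4)
  set.seed(as.integer(seed))
  x <- stats::rnorm(n)
  if (bandwidth_fraction < 1) {
    X <- stats::fft(x)
    f <- (seq_len(n) - 1) / n * fs
    f <- pmin(f, fs - f)                       # two-sided bin frequencies
    X[f > bandwidth_fraction * fs / 2] <- 0i
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  as.numeric(scale(x))
}

#' I.i.d. standard-Gaussian signal pairs
#'
#' The consistency-validation ensemble: independent pairs of i.i.d.
#' `N(0, 1)` series.
#'
#' @param n_pairs number of pairs (default 10000).
#' @param N series length.
#' @param seed integer seed.
#' @return list of `n_pairs` lists with elements `x`, `y`.
#' @export
gen_gaussian_pairs <- function(n_pairs = 10000, N = 150, seed = 1) {
  stopifnot(n_pairs >= 1, N >= 2)
  set.seed(as.integer(seed))
  lapply(seq_len(n_pairs), function(i)
    list(x = stats::rnorm(N), y = stats::rnorm(N)))
}

#' Cohort specification with a planted state schedule
#'
#' Defines a two-group synthetic cohort in which each subject follows a
#' hidden 3-state Markov chain (convergent / mixed / divergent) and the
#' channels emit amplitude disparity at the level of the current state.
#' Every channel shares one slow band-limited base signal (the common
#' network fluctuation that keeps warping paths anchored near the
#' diagonal) and adds its own independent disparity component whose
#' amplitude is the current state's level -- zero in the convergent state,
#' largest in the divergent state -- so pairwise aligned amplitude
#' differences scale with the hidden state while per-channel z-scoring
#' preserves the ordering. The default planted chain mirrors the hub
#' structure of resting-state disparity dynamics -- high self-retention,
#' transitions routed through the mixed state, no direct
#' convergent-divergent moves -- with dwell times long relative to the
#' temporal resolution of the windowed time-resolved metric.
#'
#' @param n_subjects subjects per group.
#' @param n_channels number of channels.
#' @param n_timepoints timepoints per subject.
#' @param tr sampling interval (s).
#' @param planted_P row-stochastic ergodic `3 x 3` transition matrix
#'   (states ordered convergent, mixed, divergent).
#' @param levels per-state amplitudes of the additive disparity component
#'   (units of the unit-variance base signal), strictly increasing
#'   (convergent < mixed < divergent).
#' @param base_bandwidth,disparity_bandwidth bandwidth fractions of
#'   Nyquist for the shared base and the per-channel disparity components;
#'   the base is slow (smooth, alignable), the components fast.
#' @param group2_divergent_boost added to the patient group's divergent
#'   self-retention (row renormalized): the divergence-prevalence shift.
#' @param noise_sd additive white-noise SD relative to the unit-variance
#'   base signals.
#' @param warp_amp_max maximum amplitude (in samples) of the smooth random
#'   time warp applied per channel, kept well inside the DTW window so the
#'   planted disparity is timing-confounded but resolvable.
#' @param seed integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 8, n_channels = 16, n_timepoints = 500,
                        tr = 2,
                        planted_P = rbind(c(0.980, 0.020, 0.000),
                                          c(0.015, 0.970, 0.015),
                                          c(0.000, 0.040, 0.960)),
                        levels = c(0, 0.9, 2.2),
                        base_bandwidth = 0.25,
                        disparity_bandwidth = 0.9,
                        group2_divergent_boost = 0.02,
                        noise_sd = 0.05,
                        warp_amp_max = 2,
                        seed = 1) {
  stopifnot(n_subjects >= 1, n_channels >= 2, n_timepoints >= 20,
            all(diff(levels) > 0), nrow(planted_P) == length(levels))
  if (any(abs(rowSums(planted_P) - 1) > 1e-9))
    stop("planted_P rows must sum to 1")
  if (!is_ergodic(planted_P)) stop("planted chain is not ergodic")
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 n_timepoints = n_timepoints, tr = tr,
                 planted_P = planted_P, levels = levels,
                 base_bandwidth = base_bandwidth,
                 disparity_bandwidth = disparity_bandwidth,
                 group2_divergent_boost = group2_divergent_boost,
                 noise_sd = noise_sd, warp_amp_max = warp_amp_max,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

sample_chain <- function(P, n, init_pi) {
  s <- integer(n)
  s[1] <- sample.int(length(init_pi), 1, prob = init_pi)
  for (t in 2:n) s[t] <- sample.int(ncol(P), 1, prob = P[s[t - 1], ])
  s
}

gen_cohort_group <- function(spec, P, group_id) {
  ns <- spec$n_subjects; nc <- spec$n_channels; nt <- spec$n_timepoints
  fs <- 1 / spec$tr
  pi0 <- stationary_distribution(P)
  a <- array(NA_real_, c(ns, nc, nt))
  states <- matrix(NA_integer_, ns, nt)
  tt <- seq_len(nt)
  bounded_warp <- function(base) {
    amp <- stats::runif(1, 0, spec$warp_amp_max)
    ph <- stats::runif(1, 0, 2 * pi)
    warped <- pmin(pmax(tt + amp * sin(2 * pi * tt / nt + ph), 1), nt)
    stats::approx(tt, base, xout = warped)$y
  }
  for (s in seq_len(ns)) {
    states[s, ] <- sample_chain(P, nt, pi0)
    lvl <- spec$levels[states[s, ]]
    base <- gen_band_limited_noise(spec$base_bandwidth, nt, fs,
                                   seed = sample.int(2147483646L, 1))
    for (ch in seq_len(nc)) {
      # shared slow base (with a channel-specific bounded warp: the timing
      # confound) plus an independent fast disparity component whose
      # amplitude follows the hidden state
      e <- gen_band_limited_noise(spec$disparity_bandwidth, nt, fs,
                                  seed = sample.int(2147483646L, 1))
      a[s, ch, ] <- bounded_warp(base) + lvl * bounded_warp(e) +
        spec$noise_sd * stats::rnorm(nt)
    }
  }
  list(panel = ts_panel(a, tr = spec$tr,
                        subject_ids = sprintf("g%d_sub%02d", group_id,
                                              seq_len(ns))),
       states = states)
}

#' Generate a two-group cohort with planted state dynamics
#'
#' Each subject's hidden state path is drawn from the planted chain
#' (group 2 from the divergence-boosted chain). Every channel carries an
#' independently warped copy of the subject's shared base signal plus its
#' own disparity component scaled by the current state's level, plus white
#' noise -- so the planted amplitude disparity between every channel pair
#' is timing-confounded, the condition the warping metric is designed to
#' resolve.
#'
#' @param spec a [cohort_spec].
#' @return list with `panel_group1`, `panel_group2`, and `ground_truth`
#'   (`states_group1`, `states_group2`, `P_group1`, `P_group2`, `levels`).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  P1 <- spec$planted_P
  P2 <- P1
  P2[3, 3] <- P2[3, 3] + spec$group2_divergent_boost
  P2[3, ] <- P2[3, ] / sum(P2[3, ])
  g1 <- gen_cohort_group(spec, P1, 1L)
  g2 <- gen_cohort_group(spec, P2, 2L)
  list(panel_group1 = g1$panel, panel_group2 = g2$panel,
       ground_truth = list(states_group1 = g1$states,
                           states_group2 = g2$states,
                           P_group1 = P1, P_group2 = P2,
                           levels = spec$levels))
}
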