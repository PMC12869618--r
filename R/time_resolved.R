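#' Raw time-resolved disparity trace along a warping path
#'
#' Drops the summation and normalization from nDTW: the value at path index
#' `tau` is the pointwise gamma cost of the aligned sample pair, so the mean
#' over the path reproduces `Dn` exactly.
#'
#' @param alignment a [warp_alignment][dtw_align].
#' @param gamma optional exponent; defaults to the alignment's own gamma.
#'   Supplying a different value recomputes the trace from the aligned
#'   samples (the path itself is not re-optimized).
#' @return numeric vector of length `L` with `mean(.) == alignment$Dn` when
#'   `gamma` is unchanged.
#' @export
raw_trace <- function(alignment, gamma = NULL) {
  stopifnot(inherits(alignment, "warp_alignment"))
  if (is.null(gamma) || identical(gamma, alignment$gamma))
    return(alignment$per_step_cost)
  gamma_cost(alignment$x[alignment$path[, 1]],
             alignment$y[alignment$path[, 2]], gamma)
}

#' Shape-preserving resampling of a disparity trace
#'
#' Interpolates a length-`L` path-indexed trace back to the original signal
#' length `N` with the monotone piecewise cubic Hermite interpolating
#' polynomial (PCHIP), which introduces no overshoot below the local data
#' range -- the output stays nonnegative -- and preserves first-derivative
#' continuity of the warped time scale. Query points are `N` uniformly
#' spaced abscissae spanning `[1, L]`.
#'
#' @param raw nonnegative numeric trace of length `L`.
#' @param N target length (`2 <= N <= L`).
#' @return A `disparity_trace` object: `values` (length `N`), `source_Dn`
#'   (the mean of `raw`), and `rel_diff = |mean(values) - Dn| / Dn`.
#' @export
resample_trace <- function(raw, N) {
  L <- length(raw)
  if (N < 2) stop("target length must be at least 2")
  if (L < N)
    stop(sprintf("path length L = %d shorter than target N = %d", L, N))
  Dn <- mean(raw)
  values <- if (L == N) raw else
    signal::pchip(seq_len(L), raw, seq(1, L, length.out = N))
  rel_diff <- if (Dn > 0) abs(mean(values) - Dn) / Dn else 0
  structure(list(values = values, source_Dn = Dn, rel_diff = rel_diff),
            class = "disparity_trace")
}

#' @export
print.disparity_trace <- function(x, ...) {
  cat(sprintf("disparity_trace: N = %d, Dn = %.6g, rel. consistency diff = %.4g%%\n",
              length(x$values), x$source_Dn, 100 * x$rel_diff))
  invisible(x)
}

#' Time-resolved disparity for one signal pair
#'
#' Convenience wrapper: align, take the raw trace, resample to the original
#' length.
#'
#' @inheritParams dtw_align
#' @return A [disparity_trace][resample_trace].
#' @export
disparity_trace <- function(x, y, params = dtw_params()) {
  al <- dtw_align(x, y, params)
  resample_trace(raw_trace(al), length(x))
}

#' Time-resolved disparity tensor over a panel
#'
#' Stacks [disparity_trace()] over all subjects and channel pairs.
#'
#' @param panel a [ts_panel].
#' @param params a [dtw_params].
#' @return numeric array `[n_subjects x n_pairs x n_timepoints]`; pair order
#'   as in [pair_index()]. The time-mean of each `(subject, pair)` slice
#'   reproduces the corresponding [pairwise_ndtw()] entry up to the
#'   resampling consistency bound.
#' @export
disparity_tensor <- function(panel, params = dtw_params()) {
  stopifnot(inherits(panel, "ts_panel"), n_channels(panel) >= 2)
  pi_df <- pair_index(n_channels(panel))
  nt <- n_timepoints(panel)
  out <- array(NA_real_, c(n_subjects(panel), nrow(pi_df), nt),
               dimnames = list(panel$subject_ids,
                               paste(pi_df$pair_i, pi_df$pair_j, sep = "-"),
                               NULL))
  for (s in seq_len(n_subjects(panel)))
    for (p in seq_len(nrow(pi_df))) {
      tr <- disparity_trace(panel$data[s, pi_df$pair_i[p], ],
                            panel$data[s, pi_df$pair_j[p], ], params)
      out[s, p, ] <- tr$values
    }
  out
}
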