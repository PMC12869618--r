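#' DTW parameters
#'
#' @param gamma positive exponent of the pointwise cost `|a - b|^gamma`.
#'   `gamma > 1` emphasizes large amplitude disparities, `gamma < 1` small
#'   ones; the default 1.5 favors reliability while retaining sensitivity.
#' @param window Sakoe-Chiba half-width in samples (`|i - j| <= window`), or
#'   the string `"auto"` together with `f3db`/`tr` to derive it from the
#'   low-frequency cutoff via [dtw_window_from_cutoff()].
#' @param f3db,tr used only when `window = "auto"`.
#' @return A `dtw_params` object.
#' @export
dtw_params <- function(gamma = 1.5, window = "auto", f3db = 0.01, tr = 2) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  if (identical(window, "auto"))
    window <- as.integer(dtw_window_from_cutoff(f3db, tr))
  window <- as.integer(window)
  stopifnot(window >= 1L)
  structure(list(gamma = gamma, window = window), class = "dtw_params")
}

#' Pointwise gamma cost
#'
#' `|a - b|^gamma`: the generalized distance accumulated along a warping
#' path. Vectorized over `a` and `b`.
#'
#' @param a,b numeric.
#' @param gamma positive exponent.
#' @return nonnegative numeric.
#' @examples
#' gamma_cost(3, 1, 2)    # 4
#' gamma_cost(0, 2, 0.5)  # sqrt(2)
#' @export
gamma_cost <- function(a, b, gamma) {
  stopifnot(gamma > 0)
  abs(a - b)^gamma
}

#' Window-constrained DTW alignment
#'
#' Dynamic-programming alignment of two series under the band constraint
#' `|i - j| <= w`, with anchored endpoints and the three-predecessor step
#' pattern (diagonal, vertical, horizontal; no slope weighting). Ties are
#' broken deterministically preferring the diagonal predecessor, then
#' `(i-1, j)`, then `(i, j-1)`.
#'
#' @param x,y numeric series of lengths N, M (N, M >= 2, `|N - M| <= w`).
#' @param params a [dtw_params] object.
#' @return A `warp_alignment`: `path` (`L x 2` matrix of 1-based index
#'   pairs), `per_step_cost` (the pointwise gamma cost at each path step, so
#'   `D == sum(per_step_cost)`), `D` (total distance), `L` (path length),
#'   `Dn = D / L` (normalized distance), plus the gamma and window used.
#' @examples
#' al <- dtw_align(sin(1:50), sin(1:50 + 2), dtw_params(1.5, 10))
#' al$Dn
#' @export
dtw_align <- function(x, y, params = dtw_params()) {
  stopifnot(inherits(params, "dtw_params"))
  r <- .dtw_align_cpp(as.numeric(x), as.numeric(y),
                      params$gamma, params$window)
  structure(
    list(path = cbind(ix = r$ix, iy = r$iy),
         per_step_cost = r$per_step_cost,
         D = r$D, L = r$L, Dn = r$D / r$L,
         gamma = params$gamma, window = params$window,
         x = as.numeric(x), y = as.numeric(y)),
    class = "warp_alignment")
}

#' @export
print.warp_alignment <- function(x, ...) {
  cat(sprintf("warp_alignment: L = %d (N = %d, M = %d), D = %.6g, Dn = %.6g, gamma = %g, w = %d\n",
              x$L, length(x$x), length(x$y), x$D, x$Dn, x$gamma, x$window))
  invisible(x)
}

#' Normalized DTW distance (nDTW)
#'
#' The DTW distance divided by the warping-path length: the mean aligned
#' pointwise cost, interpretable as timing-invariant amplitude disparity
#' (for `gamma = 2` it is the power of the aligned difference signal).
#' Low values indicate convergence (proportionate amplitudes), high values
#' divergence.
#'
#' @inheritParams dtw_align
#' @return nonnegative scalar `Dn`.
#' @export
ndtw <- function(x, y, params = dtw_params()) dtw_align(x, y, params)$Dn

#' Channel-pair ordering
#'
#' All unordered channel pairs in the documented order: `i < j`, `j` varying
#' fastest ((1,2), (1,3), ..., (1,K), (2,3), ...). 1-based indices.
#'
#' @param n_channels number of channels K.
#' @return data.frame with columns `pair_i`, `pair_j` (`K (K - 1) / 2` rows).
#' @export
pair_index <- function(n_channels) {
  stopifnot(n_channels >= 2)
  ij <- utils::combn(n_channels, 2)
  data.frame(pair_i = ij[1, ], pair_j = ij[2, ])
}

#' Pairwise nDTW over a panel
#'
#' Computes `Dn` for every unordered channel pair of every subject.
#'
#' @param panel a [ts_panel] with at least 2 channels.
#' @param params a [dtw_params].
#' @return numeric matrix `[n_subjects x n_pairs]` with `dimnames` from
#'   subject ids and `"i-j"` pair labels; pair order as in [pair_index()].
#' @export
pairwise_ndtw <- function(panel, params = dtw_params()) {
  stopifnot(inherits(panel, "ts_panel"), n_channels(panel) >= 2)
  pi_df <- pair_index(n_channels(panel))
  out <- matrix(NA_real_, n_subjects(panel), nrow(pi_df),
                dimnames = list(panel$subject_ids,
                                paste(pi_df$pair_i, pi_df$pair_j, sep = "-")))
  for (s in seq_len(n_subjects(panel)))
    for (p in seq_len(nrow(pi_df)))
      out[s, p] <- ndtw(panel$data[s, pi_df$pair_i[p], ],
                        panel$data[s, pi_df$pair_j[p], ], params)
  out
}

#' Write a pairwise nDTW matrix as CSV
#'
#' Long format with header `subject,pair_i,pair_j,ndtw`; 1-based channel
#' indices.
#'
#' @param mat matrix from [pairwise_ndtw()].
#' @param file output path.
#' @export
write_pairwise_csv <- function(mat, file) {
  k <- (1 + sqrt(1 + 8 * ncol(mat))) / 2
  pi_df <- pair_index(as.integer(round(k)))
  long <- data.frame(
    subject = rep(rownames(mat), each = ncol(mat)),
    pair_i = rep(pi_df$pair_i, nrow(mat)),
    pair_j = rep(pi_df$pair_j, nrow(mat)),
    ndtw = as.vector(t(mat)))
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
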