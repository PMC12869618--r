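#' Transition counts and row-stochastic matrix from a state sequence
#'
#' Counts moves `i -> j` over consecutive timepoints and row-normalizes.
#' Rows whose state was never left (zero counts) are left as all-zero and
#' flagged; such subjects are non-ergodic and are excluded from chain
#' summaries downstream (dwell time and occupancy are still defined).
#'
#' @param seq integer state labels in `1..k`.
#' @param k number of states.
#' @return A `transition_matrix`: `P` (`k x k`, rows summing to 1 or 0),
#'   `counts`, and `zero_rows` (states with no outgoing transitions).
#' @examples
#' tm <- transition_matrix(c(1, 1, 2, 2, 2, 1), k = 3)
#' tm$counts
#' @export
transition_matrix <- function(seq, k) {
  seq <- as.integer(seq)
  if (length(seq) < 2) stop("sequence must have at least 2 timepoints")
  if (any(seq < 1 | seq > k)) stop("labels outside 1..k")
  counts <- matrix(0L, k, k)
  for (t in seq_len(length(seq) - 1))
    counts[seq[t], seq[t + 1]] <- counts[seq[t], seq[t + 1]] + 1L
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  structure(list(P = P, counts = counts, zero_rows = which(rs == 0)),
            class = "transition_matrix")
}

#' Aggregate transition structure across subjects
#'
#' Default: row-normalization of the summed counts (count-weighted pooling
#' of all subjects' transitions). `method = "mean_P"` instead averages the
#' per-subject probability matrices (rows with zero counts are skipped in
#' the average).
#'
#' @param tms list of [transition_matrix] objects with equal `k`.
#' @param method `"pooled_counts"` (default) or `"mean_P"`.
#' @return A [transition_matrix] with `subject_id = "aggregate"`.
#' @export
aggregate_transitions <- function(tms, method = c("pooled_counts", "mean_P")) {
  method <- match.arg(method)
  stopifnot(length(tms) >= 1)
  k <- nrow(tms[[1]]$counts)
  if (method == "pooled_counts") {
    counts <- Reduce(`+`, lapply(tms, `[[`, "counts"))
    rs <- rowSums(counts)
    P <- counts / ifelse(rs == 0, 1, rs)
    structure(list(P = P, counts = counts, zero_rows = which(rs == 0)),
              class = "transition_matrix")
  } else {
    acc <- matrix(0, k, k); nvis <- numeric(k)
    for (tm in tms) {
      ok <- setdiff(seq_len(k), tm$zero_rows)
      acc[ok, ] <- acc[ok, ] + tm$P[ok, , drop = FALSE]
      nvis[ok] <- nvis[ok] + 1
    }
    P <- acc / ifelse(nvis == 0, 1, nvis)
    structure(list(P = P, counts = NULL, zero_rows = which(nvis == 0)),
              class = "transition_matrix")
  }
}

as_P <- function(P) {
  if (inherits(P, "transition_matrix")) P <- P$P
  stopifnot(is.matrix(P), nrow(P) == ncol(P), all(P >= -1e-12))
  P
}

#' Ergodicity check
#'
#' A finite chain is ergodic iff its transition matrix is primitive: some
#' power of the adjacency pattern (`P > 0`) is strictly positive. This
#' simultaneously captures irreducibility (strong connectivity) and
#' aperiodicity; finite irreducible chains are automatically positive
#' recurrent. Powers up to the Wielandt bound `(k - 1)^2 + 1` are checked.
#'
#' @param P row-stochastic matrix (or [transition_matrix]).
#' @return logical.
#' @export
is_ergodic <- function(P) {
  P <- as_P(P)
  k <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-9)) return(FALSE)
  A <- (P > 0) * 1
  B <- A
  for (m in seq_len((k - 1)^2 + 1)) {
    if (all(B > 0)) return(TRUE)
    B <- (B %*% A > 0) * 1
  }
  all(B > 0)
}

#' Stationary distribution
#'
#' Left eigenvector of `P` for eigenvalue 1, normalized to a probability
#' vector: the long-run occupancy of each state, satisfying `pi P = pi`.
#'
#' @param P row-stochastic ergodic matrix (or [transition_matrix]).
#' @return numeric vector `pi` (nonnegative, summing to 1).
#' @export
stationary_distribution <- function(P) {
  P <- as_P(P)
  if (!is_ergodic(P))
    stop("chain is not ergodic; exclude non-ergodic subjects before summarizing")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  pi_ <- v / sum(v)
  pi_[pi_ < 0 & pi_ > -1e-12] <- 0
  pi_ / sum(pi_)
}

#' Spectral gap
#'
#' `1 - |lambda_2|`, where `lambda_2` is the second-largest eigenvalue of
#' `P` by modulus (complex eigenvalues are handled by modulus). For an
#' ergodic chain `lambda_1 = 1` and a larger gap means faster convergence
#' to the stationary distribution.
#'
#' @param P row-stochastic ergodic matrix (or [transition_matrix]).
#' @return scalar in `[0, 1]`.
#' @export
spectral_gap <- function(P) {
  P <- as_P(P)
  if (!is_ergodic(P)) stop("chain is not ergodic")
  mods <- sort(Mod(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
  1 - mods[2]
}

#' Total-variation mixing time
#'
#' Smallest integer `t` with `TV(mu0 P^t, pi) <= tol`, where
#' `TV = 0.5 * sum(|.|)`. By default the start distribution is the simplex
#' vertex farthest from `pi` in TV distance (the indicator of the
#' least-probable state, since TV to a vertex is `1 - pi(k)`).
#'
#' @param P row-stochastic ergodic matrix (or [transition_matrix]).
#' @param pi_ stationary distribution (computed if `NULL`).
#' @param mu0 start distribution (default: farthest vertex).
#' @param tol TV tolerance (default 1e-3).
#' @param max_steps cap before a non-convergence error.
#' @return integer number of steps.
#' @export
mixing_time <- function(P, pi_ = NULL, mu0 = NULL, tol = 1e-3,
                        max_steps = 100000L) {
  P <- as_P(P)
  if (is.null(pi_)) pi_ <- stationary_distribution(P)
  if (is.null(mu0)) {
    mu0 <- numeric(length(pi_)); mu0[which.min(pi_)] <- 1
  }
  stopifnot(abs(sum(mu0) - 1) < 1e-9, all(mu0 >= 0))
  tv <- function(mu) 0.5 * sum(abs(mu - pi_))
  mu <- mu0
  if (tv(mu) <= tol) return(0L)
  for (t in seq_len(max_steps)) {
    mu <- as.numeric(mu %*% P)
    if (tv(mu) <= tol) return(as.integer(t))
  }
  stop("mixing time did not converge within ", max_steps, " steps")
}

#' Entropy rate of an ergodic chain
#'
#' `H = -sum_i pi(i) sum_j P(i,j) log2 P(i,j)` (with `0 log 0 := 0`),
#' reported both in bits and as a percentage of the maximum `log2(k)`
#' attained when every row is uniform. Low percentages indicate ordered,
#' predictable dynamics; 100\% complete randomness.
#'
#' @param P row-stochastic ergodic matrix (or [transition_matrix]).
#' @param pi_ stationary distribution (computed if `NULL`).
#' @return list with `bits` and `percent`.
#' @export
entropy_rate <- function(P, pi_ = NULL) {
  P <- as_P(P)
  if (is.null(pi_)) pi_ <- stationary_distribution(P)
  plogp <- ifelse(P > 0, P * log2(P), 0)
  H <- -sum(pi_ * rowSums(plogp))
  list(bits = H, percent = 100 * H / log2(nrow(P)))
}

#' Mean dwell time and occupancy rate
#'
#' Mean dwell time is the average maximal-run length per state (in
#' timepoints; a state never visited gets `NA`); occupancy is the
#' percentage of timepoints spent in each state (summing to 100).
#'
#' @param seq integer state labels.
#' @param k number of states (default `max(seq)`).
#' @return list with `mean_dwell` and `occupancy` (length-`k` vectors).
#' @examples
#' dwell_occupancy(c(1, 1, 2, 2, 2, 1), k = 3)
#' @export
dwell_occupancy <- function(seq, k = max(seq)) {
  seq <- as.integer(seq)
  stopifnot(length(seq) >= 1)
  r <- rle(seq)
  mean_dwell <- vapply(seq_len(k), function(s) {
    runs <- r$lengths[r$values == s]
    if (length(runs) == 0) NA_real_ else mean(runs)
  }, numeric(1))
  occ <- 100 * tabulate(seq, nbins = k) / length(seq)
  list(mean_dwell = mean_dwell, occupancy = occ)
}

#' Full chain summary
#'
#' @param P row-stochastic matrix (or [transition_matrix]).
#' @param tol TV tolerance for the mixing time.
#' @return A `chain_summary`: `pi`, `spectral_gap`, `mixing_time`,
#'   `entropy_rate_bits`, `entropy_rate_pct`, `ergodic`. Non-ergodic chains
#'   return `ergodic = FALSE` with all metrics `NA`.
#' @export
chain_summary <- function(P, tol = 1e-3) {
  P <- as_P(P)
  if (!is_ergodic(P))
    return(structure(list(ergodic = FALSE, pi = NULL, spectral_gap = NA_real_,
                          mixing_time = NA_integer_,
                          entropy_rate_bits = NA_real_,
                          entropy_rate_pct = NA_real_),
                     class = "chain_summary"))
  pi_ <- stationary_distribution(P)
  H <- entropy_rate(P, pi_)
  structure(list(ergodic = TRUE, pi = pi_,
                 spectral_gap = spectral_gap(P),
                 mixing_time = mixing_time(P, pi_, tol = tol),
                 entropy_rate_bits = H$bits, entropy_rate_pct = H$percent),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  if (!x$ergodic) { cat("chain_summary: non-ergodic\n"); return(invisible(x)) }
  cat(sprintf("chain_summary: pi = [%s], gap = %.4f, mixing time = %d, H = %.4f bits (%.1f%%)\n",
              paste(sprintf("%.4f", x$pi), collapse = ", "),
              x$spectral_gap, x$mixing_time,
              x$entropy_rate_bits, x$entropy_rate_pct))
  invisible(x)
}

#' Transition-cell perturbation analysis
#'
#' For each sampled magnitude `eps` (log-uniform over `mag_range`) and each
#' non-excluded cell `(i, j)`, increases `P[i, j]` by `eps`, renormalizes
#' row `i`, and records the percentage relative change of the spectral gap
#' and of the entropy rate. One magnitude per sample is applied uniformly
#' across all cells so cells remain comparable.
#'
#' @param P ergodic row-stochastic matrix (or [transition_matrix]).
#' @param n_samples number of sampled magnitudes (default 10000).
#' @param mag_range magnitude range (default `c(1e-3, 1e-1)`).
#' @param seed integer seed.
#' @param exclude optional logical `k x k` mask of cells to skip (e.g.
#'   structurally absent transitions).
#' @return list with `magnitudes` (length `n_samples`) and `gap_change`,
#'   `entropy_change`: `k x k x n_samples` arrays of percentage changes
#'   (`NA` for excluded cells).
#' @export
perturb_transitions <- function(P, n_samples = 10000, mag_range = c(1e-3, 1e-1),
                                seed = 1, exclude = NULL) {
  P <- as_P(P)
  if (!is_ergodic(P)) stop("chain is not ergodic")
  k <- nrow(P)
  if (is.null(exclude)) exclude <- matrix(FALSE, k, k)
  set.seed(as.integer(seed))
  eps <- exp(stats::runif(n_samples, log(mag_range[1]), log(mag_range[2])))
  gap0 <- spectral_gap(P)
  H0 <- entropy_rate(P)$bits
  gap_ch <- array(NA_real_, c(k, k, n_samples))
  ent_ch <- array(NA_real_, c(k, k, n_samples))
  for (n in seq_len(n_samples)) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (exclude[i, j]) next
      Pp <- P
      Pp[i, j] <- Pp[i, j] + eps[n]
      Pp[i, ] <- Pp[i, ] / sum(Pp[i, ])
      gap_ch[i, j, n] <- 100 * (spectral_gap(Pp) - gap0) / gap0
      ent_ch[i, j, n] <- 100 * (entropy_rate(Pp)$bits - H0) / H0
    }
  }
  list(magnitudes = eps, gap_change = gap_ch, entropy_change = ent_ch)
}
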