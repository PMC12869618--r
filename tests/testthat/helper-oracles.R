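# Independent oracles and small fixture builders used across the suite.

# Exhaustive enumeration of all monotone anchored warping paths within the
# Sakoe-Chiba band |i - j| <= w, returning the minimum total cost. Written
# independently of the DP implementation (plain recursion over successor
# moves); feasible for N, M <= 6.
brute_dtw <- function(x, y, gamma, w) {
  N <- length(x); M <- length(y)
  cost <- function(i, j) abs(x[i] - y[j])^gamma
  recurse <- function(i, j) {
    if (i == N && j == M) return(0)
    best <- Inf
    for (step in list(c(1, 1), c(1, 0), c(0, 1))) {
      ni <- i + step[1]; nj <- j + step[2]
      if (ni <= N && nj <= M && abs(ni - nj) <= w)
        best <- min(best, cost(ni, nj) + recurse(ni, nj))
    }
    best
  }
  if (abs(1 - 1) > w || abs(N - M) > w) return(Inf)
  cost(1, 1) + recurse(1, 1)
}

# Path validity: anchored, monotone steps, within window.
expect_valid_path <- function(path, N, M, w) {
  expect_equal(path[1, ], c(ix = 1, iy = 1))
  expect_equal(path[nrow(path), ], c(ix = N, iy = M))
  steps <- diff(path)
  expect_true(all(steps >= 0 & steps <= 1))
  expect_true(all(rowSums(steps) >= 1))
  expect_true(all(abs(path[, 1] - path[, 2]) <= w))
}

# Power-iteration oracle for the stationary distribution.
power_iter_pi <- function(P, tol = 1e-13, max_iter = 1e6) {
  mu <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(mu %*% P)
    if (max(abs(nxt - mu)) < tol) return(nxt)
    mu <- nxt
  }
  mu
}

# Strictly positive random row-stochastic matrix (ergodic by construction).
rand_ergodic_P <- function(k) {
  P <- matrix(stats::rgamma(k * k, shape = 1) + 1e-3, k, k)
  P / rowSums(P)
}

# Small panel of smooth random signals.
make_panel <- function(n_subjects = 1, n_channels = 3, n_timepoints = 80,
                       tr = 2, seed = 1) {
  set.seed(seed)
  a <- array(0, c(n_subjects, n_channels, n_timepoints))
  for (s in seq_len(n_subjects))
    for (ch in seq_len(n_channels))
      a[s, ch, ] <- gen_band_limited_noise(0.8, n_timepoints, 1 / tr,
                                           seed = sample.int(1e6, 1))
  ts_panel(a, tr = tr)
}

# Best label-map accuracy over all permutations of k = 3 states.
perm_accuracy <- function(labels, truth) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  accs <- apply(perms, 1, function(p) mean(p[labels] == truth))
  list(acc = max(accs), map = perms[which.max(accs), ])
}
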