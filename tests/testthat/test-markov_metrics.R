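test_that("transition counts and row normalization", {
  tm <- transition_matrix(c(1, 1, 2, 2, 2, 1), k = 3)
  expect_equal(tm$counts, rbind(c(1L, 1L, 0L), c(1L, 2L, 0L), c(0L, 0L, 0L)))
  expect_equal(tm$P[1, ], c(0.5, 0.5, 0))
  expect_equal(tm$P[2, ], c(1 / 3, 2 / 3, 0))
  expect_equal(tm$zero_rows, 3L)
  cst <- transition_matrix(rep(2, 10), k = 3)
  expect_equal(cst$P[2, 2], 1)
  expect_equal(cst$zero_rows, c(1L, 3L))
  expect_error(transition_matrix(1L, k = 2), "at least 2")
  expect_error(transition_matrix(c(1, 4), k = 3), "outside")
})

test_that("aggregation pools counts (and mean-P mode differs)", {
  t1 <- transition_matrix(c(1, 2, 1, 2), k = 2)
  t2 <- transition_matrix(c(1, 1, 1, 2), k = 2)
  agg <- aggregate_transitions(list(t1, t2))
  expect_equal(agg$counts, t1$counts + t2$counts)
  expect_equal(agg$P, (t1$counts + t2$counts) /
                 rowSums(t1$counts + t2$counts))
  aggm <- aggregate_transitions(list(t1, t2), method = "mean_P")
  expect_false(identical(agg$P, aggm$P))
  expect_equal(rowSums(aggm$P), c(1, 1))
})

test_that("ergodicity detection", {
  expect_true(is_ergodic(matrix(1 / 3, 3, 3)))
  expect_false(is_ergodic(rbind(c(0, 1), c(1, 0))))      # period 2
  expect_false(is_ergodic(diag(2)))                       # disconnected
  block <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0),
                 c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))
  expect_false(is_ergodic(block))
  # hub-structured chain with structural zeros is still ergodic
  hub <- rbind(c(0.9, 0.1, 0), c(0.05, 0.9, 0.05), c(0, 0.1, 0.9))
  expect_true(is_ergodic(hub))
})

test_that("stationary distribution solves pi P = pi", {
  expect_equal(stationary_distribution(rbind(c(0.9, 0.1), c(0.1, 0.9))),
               c(0.5, 0.5))
  set.seed(4)
  for (rep in 1:50) {
    P <- rand_ergodic_P(3)
    pi_ <- stationary_distribution(P)
    expect_equal(sum(pi_), 1, tolerance = 1e-12)
    expect_lt(max(abs(as.numeric(pi_ %*% P) - pi_)), 1e-12)
    expect_lt(max(abs(pi_ - power_iter_pi(P))), 1e-10)
  }
  expect_error(stationary_distribution(diag(3)), "not ergodic")
})

test_that("spectral gap matches closed forms", {
  expect_equal(spectral_gap(rbind(c(0.9, 0.1), c(0.1, 0.9))), 0.2)
  for (p in seq(0.01, 0.3, by = 0.03)) {
    P <- matrix(p, 3, 3); diag(P) <- 1 - 2 * p
    expect_equal(spectral_gap(P), 3 * p, tolerance = 1e-12)
  }
  expect_false(is_ergodic(diag(3)))       # identity: gap undefined, flagged
  expect_false(chain_summary(diag(3))$ergodic)
})

test_that("mixing time follows the analytic TV decay on 2-state chains", {
  P <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  pi_ <- c(0.5, 0.5)
  expect_equal(mixing_time(P, pi_, mu0 = pi_), 0L)
  # from a vertex, TV after t steps is 0.5 * (1 - 2p)^t
  for (tol in c(1e-2, 1e-3, 1e-4)) {
    expected <- ceiling(log(2 * tol) / log(0.8))
    expect_equal(mixing_time(P, pi_, mu0 = c(1, 0), tol = tol),
                 as.integer(expected))
  }
  expect_equal(mixing_time(P, pi_, mu0 = c(1, 0), tol = 1e-3), 28L)
  # default initializer: the vertex of the least-probable state maximizes
  # TV over simplex vertices (TV to a vertex is 1 - pi(k))
  P3 <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.15, 0.8))
  pi3 <- stationary_distribution(P3)
  k_far <- which.min(pi3)
  expect_equal(1 - pi3[k_far], max(1 - pi3))
  t_def <- mixing_time(P3)
  mu0 <- numeric(3); mu0[k_far] <- 1
  expect_equal(t_def, mixing_time(P3, pi3, mu0 = mu0))
  expect_error(mixing_time(P, pi_, mu0 = c(1, 0), tol = 0, max_steps = 10),
               "did not converge")
})

test_that("entropy rate in bits and percent", {
  u <- entropy_rate(matrix(1 / 3, 3, 3))
  expect_equal(u$bits, log2(3), tolerance = 1e-12)
  expect_equal(round(u$bits, 4), 1.585)
  expect_equal(u$percent, 100)
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(entropy_rate(cyc, pi_ = rep(1 / 3, 3))$bits, 0)
  two <- entropy_rate(rbind(c(0.9, 0.1), c(0.1, 0.9)))
  expect_equal(two$bits, -(0.9 * log2(0.9) + 0.1 * log2(0.1)),
               tolerance = 1e-12)
  expect_equal(round(two$bits, 4), 0.469)
  # percent is in [0, 100], 100 only for uniform rows
  set.seed(9)
  for (rep in 1:20) {
    pc <- entropy_rate(rand_ergodic_P(3))$percent
    expect_gte(pc, 0); expect_lt(pc, 100)
  }
})

test_that("dwell time and occupancy from run-length structure", {
  d <- dwell_occupancy(c(1, 1, 2, 2, 2, 1), k = 3)
  expect_equal(d$mean_dwell, c(1.5, 3, NA))
  expect_equal(d$occupancy, c(50, 50, 0))
  cst <- dwell_occupancy(rep(2, 7), k = 2)
  expect_equal(cst$mean_dwell, c(NA, 7))
  expect_equal(cst$occupancy, c(0, 100))
  alt <- dwell_occupancy(rep(c(1, 2), 5), k = 2)
  expect_equal(alt$mean_dwell, c(1, 1))
  expect_equal(sum(alt$occupancy), 100)
})

test_that("chain summary ties the metrics together", {
  P <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.15, 0.8))
  cs <- chain_summary(P)
  expect_true(cs$ergodic)
  expect_equal(as.numeric(cs$pi %*% P), cs$pi, tolerance = 1e-12)
  expect_equal(cs$spectral_gap, spectral_gap(P))
  expect_equal(cs$entropy_rate_pct,
               100 * cs$entropy_rate_bits / log2(3))
})

test_that("transition perturbation: self-retention slows mixing", {
  P <- matrix(0.1, 3, 3); diag(P) <- 0.8
  res <- perturb_transitions(P, n_samples = 40, seed = 3)
  expect_length(res$magnitudes, 40)
  expect_true(all(res$magnitudes >= 1e-3 & res$magnitudes <= 1e-1))
  for (i in 1:3)
    expect_true(all(res$gap_change[i, i, ] < 0))
  # entropy also drops when a row becomes more deterministic
  expect_true(all(res$entropy_change[1, 1, ] < 0))
  # determinism and exclusion mask
  res_b <- perturb_transitions(P, n_samples = 40, seed = 3)
  expect_identical(res$gap_change, res_b$gap_change)
  mask <- matrix(FALSE, 3, 3); mask[1, 3] <- TRUE
  res_m <- perturb_transitions(P, n_samples = 5, seed = 1, exclude = mask)
  expect_true(all(is.na(res_m$gap_change[1, 3, ])))
  expect_false(anyNA(res_m$gap_change[2, , ]))
  # vanishing magnitudes produce vanishing changes
  tiny <- perturb_transitions(P, n_samples = 5, mag_range = c(1e-9, 1e-8),
                              seed = 2)
  expect_lt(max(abs(tiny$gap_change)), 1e-4)
})

test_that("chains sampled from a known P recover it within sampling error", {
  set.seed(21)
  P <- rbind(c(0.9, 0.1, 0), c(0.05, 0.9, 0.05), c(0, 0.1, 0.9))
  pi_ <- stationary_distribution(P)
  sim_chain <- function(n) {
    s <- integer(n); s[1] <- sample.int(3, 1, prob = pi_)
    for (t in 2:n) s[t] <- sample.int(3, 1, prob = P[s[t - 1], ])
    s
  }
  tms <- lapply(1:20, function(i) transition_matrix(sim_chain(500), 3))
  agg <- aggregate_transitions(tms)
  se <- sqrt(P * (1 - P) / rowSums(agg$counts))
  dev <- abs(agg$P - P) / pmax(se, 1e-9)
  expect_lt(max(dev[P > 0]), 3)
  expect_equal(agg$P[1, 3], 0)            # structural zeros stay zero
  expect_equal(agg$P[3, 1], 0)
})
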