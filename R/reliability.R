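#' Within-subject session variability
#'
#' Paired-sample absolute t statistic per pair between two sessions:
#' `|mean(d)| / (sd(d) / sqrt(n))` with `d = session1 - session2`. Lower
#' values mean higher within-subject consistency. The degenerate `0/0` case
#' (sessions identical) is defined as 0 (perfect consistency); a nonzero
#' mean with zero spread yields an `Inf` sentinel with a warning.
#'
#' @param session1,session2 numeric matrices `[n_subjects x n_pairs]` with
#'   matching subjects and pairs; `n >= 3`.
#' @param sqrt_n if `FALSE`, scale by `n` instead of `sqrt(n)` (the literal
#'   reading of the printed formula; default follows the t-test convention).
#' @return per-pair nonnegative vector.
#' @export
within_subject_stat <- function(session1, session2, sqrt_n = TRUE) {
  stopifnot(identical(dim(session1), dim(session2)), nrow(session1) >= 3)
  n <- nrow(session1)
  d <- session1 - session2
  m <- abs(colMeans(d))
  s <- apply(d, 2, stats::sd)
  denom <- if (sqrt_n) s / sqrt(n) else s / n
  out <- ifelse(s == 0 & m == 0, 0,
                ifelse(s == 0, Inf, m / denom))
  if (any(is.infinite(out)))
    warning("zero-variance nonzero differences: Inf sentinel returned for ",
            sum(is.infinite(out)), " pair(s)")
  out
}

#' Between-subject variability (non-parametric)
#'
#' Robust analogue of the absolute t statistic on a single session: with
#' `d_i = |s_i - mean(s)|`, the statistic is
#' `median(d) / (IQR(d) / sqrt(n))`. Zero IQR (including the all-identical
#' degenerate case) yields an `Inf` sentinel with a warning.
#'
#' @param session1 numeric matrix `[n_subjects x n_pairs]`, `n >= 4`.
#' @param sqrt_n as in [within_subject_stat()].
#' @return per-pair nonnegative vector.
#' @export
between_subject_stat <- function(session1, sqrt_n = TRUE) {
  stopifnot(nrow(session1) >= 4)
  n <- nrow(session1)
  d <- abs(sweep(session1, 2, colMeans(session1)))
  med <- apply(d, 2, stats::median)
  iqr <- apply(d, 2, stats::IQR)
  denom <- if (sqrt_n) iqr / sqrt(n) else iqr / n
  out <- ifelse(iqr == 0, Inf, med / denom)
  if (any(is.infinite(out)))
    warning("zero-IQR differences: Inf sentinel returned for ",
            sum(is.infinite(out)), " pair(s)")
  out
}

#' Composite test-retest reliability score
#'
#' `trt = 1 - |t|within / |t|between` per pair; scores approaching 1
#' indicate higher test-retest reliability. Both component statistics are
#' individually scale-invariant, so `trt` is invariant to a common positive
#' rescaling of the metric.
#'
#' @param session1,session2 `[n_subjects x n_pairs]` metric matrices.
#' @param sqrt_n as in [within_subject_stat()].
#' @return list with `t_within`, `t_between`, `trt`.
#' @export
trt_score <- function(session1, session2, sqrt_n = TRUE) {
  tw <- within_subject_stat(session1, session2, sqrt_n = sqrt_n)
  tb <- between_subject_stat(session1, sqrt_n = sqrt_n)
  trt <- ifelse(tb > 0, 1 - tw / tb, NA_real_)
  list(t_within = tw, t_between = tb, trt = trt)
}

#' Compare reliability between two methods
#'
#' Ranks the per-pair trt scores of two methods (rank 1 = more reliable,
#' i.e. higher trt, within each pair) and tests the paired difference with
#' a Wilcoxon signed-rank test.
#'
#' @param trt_a,trt_b per-pair trt vectors over the same pair set.
#' @return list with `mean_rank_a`, `mean_rank_b` (lower = more reliable)
#'   and `p` (paired signed-rank p-value).
#' @export
trt_compare <- function(trt_a, trt_b) {
  stopifnot(length(trt_a) == length(trt_b))
  ranks <- apply(cbind(trt_a, trt_b), 1, function(z) rank(-z))
  p <- if (isTRUE(all.equal(trt_a, trt_b))) 1 else
    stats::wilcox.test(trt_a, trt_b, paired = TRUE, exact = FALSE)$p.value
  list(mean_rank_a = mean(ranks[1, ]), mean_rank_b = mean(ranks[2, ]), p = p)
}
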