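#' Trim alignment-anchored edges from a disparity tensor
#'
#' DTW anchors the first and last timepoints, which biases the trace at the
#' temporal extremes; the first and last `trim` timepoints are therefore
#' excluded before clustering.
#'
#' @param tensor array `[n_subjects x n_pairs x N]` from
#'   [disparity_tensor()].
#' @param trim timepoints removed from each end (default 5).
#' @return the shortened tensor (`N - 2 * trim` timepoints).
#' @export
trim_edges <- function(tensor, trim = 5) {
  stopifnot(length(dim(tensor)) == 3, trim >= 0)
  nt <- dim(tensor)[3]
  if (trim == 0) return(tensor)
  if (nt <= 2 * trim)
    stop(sprintf("too few timepoints (%d) to trim %d from each end", nt, trim))
  tensor[, , (trim + 1):(nt - trim), drop = FALSE]
}

## Lloyd-type k-means under the city-block (L1) objective: assignment by
## Manhattan distance, centroid update by the per-feature median (the
## L1-optimal centroid). `centroid = "mean"` reproduces toolbox variants
## that keep the mean update. The Lloyd loop runs in compiled code.
kmeans_cityblock <- function(X, k, max_iter = 10000, centroid = "median") {
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of samples")
  Xt <- t(X)
  init_t <- Xt[, sample.int(n, k), drop = FALSE]
  fit <- .kmeans_l1_cpp(Xt, init_t, as.integer(max_iter),
                        identical(centroid, "median"))
  list(centroids = t(fit$centroids_t), labels = as.integer(fit$labels),
       wss = fit$wss)
}

#' Fit recurring disparity states by city-block k-means
#'
#' Concatenates all subjects' trimmed timepoints into one sample matrix
#' (rows = timepoints, columns = channel pairs) and fits k-means under the
#' city-block distance for every candidate `k`, keeping the best of `reps`
#' random initializations per `k`. The within-cluster sum of (city-block)
#' distances is recorded per `k` as the WSS curve for elbow selection.
#'
#' @param tensor trimmed disparity tensor `[n_subjects x n_pairs x T]`.
#' @param k_range candidate cluster counts (default 1:10).
#' @param reps random initializations per `k` (default 20).
#' @param max_iter Lloyd iteration cap (default 10000).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param centroid `"median"` (L1-optimal, default) or `"mean"`.
#' @return A `state_model`: `k` (elbow-selected, see [select_k_elbow()]),
#'   `wss_curve`, `k_range`, per-`k` `fits` (centroids `[k x n_pairs]` and
#'   concatenated labels), and the `n_subjects`/`n_time` layout needed to
#'   split labels back into per-subject sequences.
#' @export
fit_states <- function(tensor, k_range = 1:10, reps = 20,
                       max_iter = 10000, seed = 1, centroid = "median") {
  stopifnot(length(dim(tensor)) == 3)
  ns <- dim(tensor)[1]; np <- dim(tensor)[2]; nt <- dim(tensor)[3]
  X <- do.call(rbind, lapply(seq_len(ns), function(s)
    matrix(tensor[s, , ], nrow = nt, ncol = np, byrow = TRUE)))
  if (any(!is.finite(X))) stop("tensor contains non-finite values")
  fits <- vector("list", length(k_range))
  wss <- numeric(length(k_range))
  for (m in seq_along(k_range)) {
    k <- k_range[m]
    best <- NULL
    for (r in seq_len(reps)) {
      set.seed(as.integer(seed) + 1000L * m + r)
      fit <- kmeans_cityblock(X, k, max_iter = max_iter, centroid = centroid)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
    fits[[m]] <- best
    wss[m] <- best$wss
  }
  sel <- if (length(k_range) >= 4) select_k_elbow(wss, k_range) else
    structure(k_range[length(k_range)], no_elbow = FALSE)
  structure(list(k = as.integer(sel), wss_curve = wss, k_range = k_range,
                 no_elbow = isTRUE(attr(sel, "no_elbow")),
                 fits = fits, n_subjects = ns, n_time = nt,
                 pair_labels = dimnames(tensor)[[2]],
                 subject_ids = dimnames(tensor)[[1]]),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d selected over k in {%s}%s\n",
              x$k, paste(range(x$k_range), collapse = ".."),
              if (x$no_elbow) " (no clear elbow)" else ""))
  cat("WSS:", signif(x$wss_curve, 4), "\n")
  invisible(x)
}

#' Elbow selection on a WSS curve
#'
#' Picks the first point of maximal curvature of the WSS curve relative to
#' the slope that follows it: with `d2(k) = wss(k+1) - 2 wss(k) + wss(k-1)`
#' and `d1(k+1) = wss(k+1) - wss(k)`, the score is `d2(k) / |d1(k+1)|`, and
#' the selected `k` is the first argmax. This ratio is large exactly where
#' the steep initial descent of the curve gives way to a flat tail -- the
#' elbow -- and is invariant to rescaling of the WSS. A curve with no
#' positive curvature (monotone linear) yields the first candidate with a
#' `no_elbow` attribute and a warning.
#'
#' @param wss_curve WSS per candidate `k` (length >= 4).
#' @param k_range the candidate `k` values (default `seq_along(wss_curve)`).
#' @return selected `k` (integer, attribute `no_elbow`).
#' @examples
#' select_k_elbow(c(100, 40, 20, 18, 17, 16.5))  # 3
#' @export
select_k_elbow <- function(wss_curve, k_range = seq_along(wss_curve)) {
  K <- length(wss_curve)
  stopifnot(K >= 4, length(k_range) == K)
  scale <- max(wss_curve[1] - wss_curve[K], .Machine$double.eps)
  idx <- 2:(K - 1)
  d2 <- wss_curve[idx + 1] - 2 * wss_curve[idx] + wss_curve[idx - 1]
  d1_next <- abs(wss_curve[idx + 1] - wss_curve[idx])
  score <- d2 / pmax(d1_next, 1e-12 * scale)
  if (max(d2) <= 1e-8 * scale) {
    warning("WSS curve has no discernible elbow")
    return(structure(as.integer(k_range[idx[1]]), no_elbow = TRUE))
  }
  structure(as.integer(k_range[idx[which.max(score)]]), no_elbow = FALSE)
}

#' Per-subject state sequences
#'
#' @param model a [state_model][fit_states].
#' @param k cluster count (default the model's selected `k`).
#' @return list of integer label vectors (one per subject, values `1..k`).
#' @export
state_sequences <- function(model, k = model$k) {
  m <- match(k, model$k_range)
  if (is.na(m)) stop("k = ", k, " was not fitted")
  lab <- model$fits[[m]]$labels
  split(lab, rep(seq_len(model$n_subjects), each = model$n_time))
}

#' Orient states for display and assign roles
#'
#' Display-only transformation: subtracts the median over all centroid
#' entries and flips the sign, so positive display values represent
#' convergence (low disparity) and negative values divergence. States are
#' ranked by their mean display value: the highest is labelled
#' `"convergent"`, the lowest `"divergent"`, intermediate states `"mixed"`;
#' ties break deterministically by state index. Raw centroids are returned
#' untouched.
#'
#' @param model a [state_model][fit_states].
#' @param k cluster count (default the model's selected `k`).
#' @return list with `centroids` (raw), `display` (oriented), `roles`
#'   (character per state), and `ranking` (state indices from most
#'   convergent to most divergent).
#' @export
orient_states <- function(model, k = model$k) {
  m <- match(k, model$k_range)
  if (is.na(m)) stop("k = ", k, " was not fitted")
  cent <- model$fits[[m]]$centroids
  display <- -(cent - stats::median(cent))
  means <- rowMeans(display)
  ranking <- order(-means, seq_len(k))   # ties by state index
  roles <- rep("mixed", k)
  roles[ranking[1]] <- "convergent"
  roles[ranking[k]] <- "divergent"
  list(centroids = cent, display = display, roles = roles, ranking = ranking)
}

#' Threshold a display centroid into its dominant pair map
#'
#' For convergent/divergent states, returns the `ceil(top_fraction *
#' n_pairs)` pairs with the strongest display values of the dominant sign
#' (positive for convergent, negative for divergent). For the mixed state,
#' returns the union of the top `top_fraction / 2` positive and top
#' `top_fraction / 2` negative pairs.
#'
#' @param display_centroid numeric display-row for one state.
#' @param role `"convergent"`, `"divergent"` or `"mixed"`.
#' @param top_fraction fraction in (0, 1), default 0.05.
#' @return integer vector of selected pair indices (possibly empty, with a
#'   warning, for an all-zero centroid).
#' @export
state_pair_map <- function(display_centroid,
                           role = c("convergent", "divergent", "mixed"),
                           top_fraction = 0.05) {
  role <- match.arg(role)
  stopifnot(top_fraction > 0, top_fraction < 1)
  np <- length(display_centroid)
  if (all(display_centroid == 0)) {
    warning("all-zero display centroid: empty pair map")
    return(integer(0))
  }
  top_of <- function(v, n_top, sign) {
    keep <- which(sign * v > 0)
    keep[order(-sign * v[keep])][seq_len(min(n_top, length(keep)))]
  }
  if (role == "mixed") {
    n_top <- ceiling(top_fraction / 2 * np)
    sort(union(top_of(display_centroid, n_top, +1),
               top_of(display_centroid, n_top, -1)))
  } else {
    n_top <- ceiling(top_fraction * np)
    sgn <- if (role == "convergent") +1 else -1
    sort(top_of(display_centroid, n_top, sgn))
  }
}
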