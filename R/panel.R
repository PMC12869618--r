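#' Multichannel time-series panel
#'
#' The universal input container: a `n_subjects x n_channels x n_timepoints`
#' numeric array together with the sampling interval (TR, seconds per
#' sample) and the frequency band the data currently occupy.
#'
#' @param data numeric array `[n_subjects, n_channels, n_timepoints]`, or a
#'   `channels x timepoints` matrix for a single subject.
#' @param tr sampling interval in seconds (repetition time).
#' @param band either the string `"raw"` (unfiltered) or a numeric pair
#'   `c(f_lo, f_hi)` in Hz with `0 < f_lo < f_hi <= 1/(2 tr)`.
#' @param channel_labels,subject_ids optional character labels; defaults
#'   `ch1..chK` and `sub1..subS`.
#' @return An object of class `ts_panel`.
#' @examples
#' x <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
#' p <- ts_panel(x, tr = 2)
#' dim(p)
#' @export
ts_panel <- function(data, tr, band = "raw",
                     channel_labels = NULL, subject_ids = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a [subjects x channels x timepoints] array")
  if (dim(data)[3] < 2L) stop("need at least 2 timepoints")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive scalar (seconds per sample)")
  if (!identical(band, "raw")) {
    if (!is.numeric(band) || length(band) != 2L)
      stop("'band' must be \"raw\" or c(f_lo, f_hi)")
    nyq <- 1 / (2 * tr)
    if (!(0 < band[1] && band[1] < band[2] && band[2] <= nyq))
      stop(sprintf("band must satisfy 0 < f_lo < f_hi <= Nyquist = %g Hz", nyq))
  }
  if (anyNA(data) || any(!is.finite(data)))
    stop("panel data contain non-finite values")
  ns <- dim(data)[1]; nc <- dim(data)[2]
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nc))
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(ns))
  stopifnot(length(channel_labels) == nc, length(subject_ids) == ns)
  structure(
    list(data = data, tr = tr, band = band,
         channel_labels = as.character(channel_labels),
         subject_ids = as.character(subject_ids)),
    class = "ts_panel")
}

#' @export
dim.ts_panel <- function(x) dim(x$data)

#' @export
print.ts_panel <- function(x, ...) {
  d <- dim(x$data)
  bd <- if (identical(x$band, "raw")) "raw"
        else sprintf("%.3g-%.3g Hz", x$band[1], x$band[2])
  cat(sprintf("ts_panel: %d subject(s) x %d channel(s) x %d timepoint(s), TR = %g s, band = %s\n",
              d[1], d[2], d[3], x$tr, bd))
  invisible(x)
}

n_subjects <- function(panel) dim(panel$data)[1]
n_channels <- function(panel) dim(panel$data)[2]
n_timepoints <- function(panel) dim(panel$data)[3]

#' Write / read a panel as delimited text plus a manifest
#'
#' One tab-separated file per subject (`channels x timepoints`, header row of
#' channel labels is stored transposed as `timepoints x channels` for
#' readability) and a JSON manifest recording TR, band, subject files and
#' labels.
#'
#' @param panel a [ts_panel].
#' @param dir output directory (created if missing).
#' @return `write_panel` returns the manifest path invisibly; `read_panel`
#'   returns a [ts_panel].
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(n_subjects(panel))
  for (s in seq_len(n_subjects(panel))) {
    files[s] <- paste0(gsub("[^A-Za-z0-9_.-]", "_", panel$subject_ids[s]), ".tsv")
    m <- t(panel$data[s, , , drop = TRUE])
    if (n_channels(panel) == 1L) m <- matrix(panel$data[s, 1, ], ncol = 1)
    colnames(m) <- panel$channel_labels
    utils::write.table(m, file.path(dir, files[s]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- list(tr = panel$tr,
                   band = if (identical(panel$band, "raw")) "raw" else panel$band,
                   subject_ids = panel$subject_ids,
                   files = files,
                   channel_labels = panel$channel_labels)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  mats <- lapply(man$files, function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("missing subject file: ", fp)
    as.matrix(utils::read.table(fp, header = TRUE, sep = "\t",
                                check.names = FALSE))
  })
  nt <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  a <- array(NA_real_, c(length(mats), nc, nt))
  for (s in seq_along(mats)) a[s, , ] <- t(mats[[s]])
  band <- if (identical(man$band, "raw")) "raw" else as.numeric(man$band)
  ts_panel(a, tr = man$tr, band = band,
           channel_labels = man$channel_labels, subject_ids = man$subject_ids)
}
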