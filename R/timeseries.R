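#' One subject's ROI time-series matrix
#'
#' Wraps a T x N signal matrix (rows = time points at a fixed repetition time,
#' columns = ROIs in [roi_set] order) with its subject identifier and TR.
#' Non-finite values are rejected; short series (T < N + 2, where sample
#' correlation matrices become rank-deficient) trigger a warning.
#'
#' @param subject_id Subject identifier string.
#' @param data Numeric T x N matrix; column names, if present, are kept.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @return An object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(subject_id, data, tr_seconds) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, nzchar(subject_id))
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("time series for subject ", subject_id, " contains non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  if (nrow(data) < ncol(data) + 2L)
    warning("subject ", subject_id, ": only ", nrow(data),
            " time points for ", ncol(data),
            " ROIs; correlation estimates will be unstable")
  structure(list(subject_id = subject_id, data = data,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "subject_timeseries")
}

#' @export
print.subject_timeseries <- function(x, ...) {
  cat("subject_timeseries '", x$subject_id, "': ", nrow(x$data),
      " time points x ", ncol(x$data), " ROIs, TR = ", x$tr_seconds,
      " s\n", sep = "")
  invisible(x)
}

.ts_matrix <- function(x) {
  if (inherits(x, "subject_timeseries")) x$data else as.matrix(x)
}

#' Z-score each ROI column
#'
#' Column-wise standardization (mean 0, sd 1). Pearson correlation is
#' invariant to this, but it stabilizes the Fisher-z computation path and
#' puts epoch slices from the same run on a common scale.
#'
#' @param ts A [subject_timeseries] or plain matrix.
#' @return Same type as the input.
#' @export
standardize_columns <- function(ts) {
  m <- .ts_matrix(ts)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("cannot standardize constant column(s): ",
         paste(.col_labels(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (inherits(ts, "subject_timeseries")) {
    ts$data <- z
    ts
  } else z
}

.col_labels <- function(m) {
  if (!is.null(colnames(m))) colnames(m) else paste0("node", seq_len(ncol(m)))
}

#' Extract an epoch slice from a subject time series
#'
#' @param ts A [subject_timeseries].
#' @param tr_window Half-open 0-based TR index interval `c(start, end)`, as
#'   produced by [epochs_to_tr()].
#' @param standardize Z-score columns within the slice (default `TRUE`).
#' @return A [subject_timeseries] restricted to the window.
#' @export
slice_epoch <- function(ts, tr_window, standardize = TRUE) {
  stopifnot(inherits(ts, "subject_timeseries"), length(tr_window) == 2L)
  start <- tr_window[1L]; end <- tr_window[2L]
  if (start < 0 || end > nrow(ts$data) || end <= start)
    stop("TR window [", start, ", ", end, ") outside run of length ",
         nrow(ts$data))
  out <- subject_timeseries(ts$subject_id,
                            ts$data[(start + 1L):end, , drop = FALSE],
                            ts$tr_seconds)
  if (standardize) out <- standardize_columns(out)
  out
}
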