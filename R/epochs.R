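#' Continuous emotion-rating trace for one subject
#'
#' Ratings are sampled at a fixed rate (10 Hz in the emulated design) on a
#' discrete intensity scale with `scale_levels` degrees (21 in the emulated
#' design, i.e. values in \[0, 20\]). Gaps must be interpolated before
#' construction; non-finite samples are rejected.
#'
#' @param subject_id Subject identifier.
#' @param samples Numeric vector of intensity samples.
#' @param rate_hz Sampling rate in Hz (> 0); default 10.
#' @param scale_levels Number of discrete scale degrees; default 21.
#' @return Object of class `rating_trace`.
#' @export
rating_trace <- function(subject_id, samples, rate_hz = 10, scale_levels = 21) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty rating trace")
  if (any(!is.finite(samples)))
    stop("rating trace for subject ", subject_id,
         " has non-finite samples; interpolate gaps first")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (any(samples < 0 | samples > scale_levels - 1))
    stop("samples outside [0, ", scale_levels - 1, "] for subject ",
         subject_id)
  structure(list(subject_id = as.character(subject_id), samples = samples,
                 rate_hz = as.numeric(rate_hz),
                 scale_levels = as.integer(scale_levels)),
            class = "rating_trace")
}

#' @export
print.rating_trace <- function(x, ...) {
  cat("rating_trace '", x$subject_id, "': ", length(x$samples),
      " samples @ ", x$rate_hz, " Hz (",
      round(length(x$samples) / x$rate_hz, 1), " s)\n", sep = "")
  invisible(x)
}

#' Area-under-the-curve intensity index
#'
#' Trapezoidal integral of the rating trace over time, in scale-units x
#' seconds; sample i sits at time (i - 1) / rate_hz. Higher AUC means more
#' reported intensity over the whole stimulus.
#'
#' @param trace A [rating_trace] with >= 2 samples.
#' @return Scalar AUC.
#' @export
rating_auc <- function(trace) {
  stopifnot(inherits(trace, "rating_trace"))
  n <- length(trace$samples)
  if (n < 2L) stop("AUC needs at least 2 samples")
  t <- (seq_len(n) - 1) / trace$rate_hz
  pracma::trapz(t, trace$samples)
}

.trace_matrix <- function(traces) {
  if (is.matrix(traces)) return(traces)
  stopifnot(is.list(traces), length(traces) > 0L)
  lens <- vapply(traces, function(tr) length(tr$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("rating traces differ in length: ",
         paste(range(lens), collapse = " vs "))
  rates <- vapply(traces, function(tr) tr$rate_hz, numeric(1))
  if (length(unique(rates)) != 1L)
    stop("rating traces differ in sampling rate")
  m <- vapply(traces, function(tr) tr$samples, numeric(lens[1L]))
  if (!is.matrix(m)) m <- matrix(m, ncol = length(traces))
  colnames(m) <- vapply(traces, function(tr) tr$subject_id, character(1))
  m
}

#' Pointwise median rating across subjects
#'
#' @param traces List of equal-length, equal-rate [rating_trace]s (or a
#'   samples x subjects matrix).
#' @return Numeric vector: the group median at every sample. Even subject
#'   counts use the mean-of-middle-two convention of [stats::median()].
#' @export
median_trace <- function(traces) {
  m <- .trace_matrix(traces)
  apply(m, 1L, stats::median)
}

.window_stat <- function(x, start, len) stats::median(x[start:(start + len - 1L)])

# Wilcoxon signed-rank p for one candidate window pair.
# subjects mode: per-subject window medians paired across subjects;
# timepoints mode: median-trace samples paired by within-window position.
.pair_wilcoxon <- function(m, med, s_lo, s_hi, len, pairing) {
  if (pairing == "subjects") {
    lo <- apply(m[s_lo:(s_lo + len - 1L), , drop = FALSE], 2L, stats::median)
    hi <- apply(m[s_hi:(s_hi + len - 1L), , drop = FALSE], 2L, stats::median)
  } else {
    lo <- med[s_lo:(s_lo + len - 1L)]
    hi <- med[s_hi:(s_hi + len - 1L)]
  }
  if (all(hi == lo)) return(1)
  out <- tryCatch(
    suppressWarnings(stats::wilcox.test(hi, lo, paired = TRUE)),
    error = function(e) NULL)
  if (is.null(out) || is.na(out$p.value)) 1 else out$p.value
}

#' Search for a maximal pair of contrasting epochs
#'
#' Implements the epoch definition used for continuous ratings: find one
#' low- and one high-intensity window that (1) are equal in length, (2)
#' differ significantly in median ratings across subjects by Wilcoxon
#' signed-rank test at `alpha`, and (3) are as long as possible, starting
#' from half the trace and iterating downwards. At the largest passing
#' length, among all non-overlapping window pairs passing the Wilcoxon
#' criterion the pair maximizing (high-window median - low-window median) of
#' the group median trace is returned; ties break on the earliest high-window
#' start, then the earliest low-window start.
#'
#' @param traces List of [rating_trace]s (equal length and rate).
#' @param alpha Wilcoxon significance threshold; default 0.01.
#' @param pairing `"subjects"` (default): the test pairs per-subject window
#'   medians across subjects. `"timepoints"`: pairs group-median samples by
#'   within-window position.
#' @param step Search stride in samples for both window starts and candidate
#'   lengths. Defaults to one second of samples (`round(rate_hz)`); set to 1
#'   for exhaustive sample-level search on short traces.
#' @return Object of class `epoch_pair` with second-resolution half-open
#'   windows `low_window` / `high_window` = `c(start_s, end_s)`, `length_s`,
#'   and the achieved `wilcoxon_p`. TR windows are added by [epochs_to_tr()].
#' @export
find_epoch_pair <- function(traces, alpha = 0.01,
                            pairing = c("subjects", "timepoints"),
                            step = NULL) {
  pairing <- match.arg(pairing)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  m <- .trace_matrix(traces)
  rate <- if (is.list(traces)) traces[[1L]]$rate_hz else 1
  n <- nrow(m)
  if (is.null(step)) step <- max(1L, as.integer(round(rate)))
  step <- as.integer(step)
  med <- apply(m, 1L, stats::median)
  if (diff(range(med)) == 0)
    stop("no separable epochs: the group median trace is constant")
  lens <- seq.int(from = (n %/% 2L), to = step, by = -step)
  if (length(lens) < 1L) stop("trace too short for the epoch search")
  for (len in lens) {
    starts <- seq.int(1L, n - len + 1L, by = step)
    wmed <- vapply(starts, .window_stat, numeric(1), x = med, len = len)
    # all non-overlapping ordered pairs (a before b), adjacency allowed
    grid <- which(outer(starts + len, starts, `<=`), arr.ind = TRUE)
    if (nrow(grid) == 0L) next
    a <- grid[, 1L]; b <- grid[, 2L]
    dmed <- abs(wmed[b] - wmed[a])
    keep <- dmed > 0
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]; dmed <- dmed[keep]
    hi <- ifelse(wmed[b] >= wmed[a], b, a)
    lo <- ifelse(wmed[b] >= wmed[a], a, b)
    ord <- order(-dmed, starts[hi], starts[lo])
    for (idx in ord) {
      p <- .pair_wilcoxon(m, med, starts[lo[idx]], starts[hi[idx]], len,
                          pairing)
      if (p < alpha) {
        to_s <- function(s) (s - 1) / rate
        return(structure(list(
          low_window = c(to_s(starts[lo[idx]]), to_s(starts[lo[idx]] + len)),
          high_window = c(to_s(starts[hi[idx]]), to_s(starts[hi[idx]] + len)),
          length_s = len / rate,
          wilcoxon_p = p,
          pairing = pairing,
          alpha = alpha,
          tr_windows = NULL), class = "epoch_pair"))
      }
    }
  }
  stop("no separable epochs: no window pair met the Wilcoxon criterion ",
       "at alpha = ", alpha)
}

#' @export
print.epoch_pair <- function(x, ...) {
  cat("epoch_pair: length ", x$length_s, " s, Wilcoxon p = ",
      signif(x$wilcoxon_p, 3), "\n  low  [", x$low_window[1L], ", ",
      x$low_window[2L], ") s\n  high [", x$high_window[1L], ", ",
      x$high_window[2L], ") s\n", sep = "")
  if (!is.null(x$tr_windows))
    cat("  TR windows: low [", x$tr_windows$low[1L], ", ",
        x$tr_windows$low[2L], "), high [", x$tr_windows$high[1L], ", ",
        x$tr_windows$high[2L], ") @ TR ", x$tr_windows$tr_seconds,
        " s\n", sep = "")
  invisible(x)
}

#' Map epoch windows onto TR (volume) indices
#'
#' Converts second-resolution windows to half-open 0-based TR-index windows
#' via `floor((t + lag) / tr)`. Both windows are forced to the same TR count
#' by truncating the longer one at its end. An optional hemodynamic lag
#' shifts both windows forward in time before conversion.
#'
#' @param pair An `epoch_pair` from [find_epoch_pair()].
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param lag_seconds Hemodynamic lag added to both windows; default 0.
#' @return The `epoch_pair` with a `tr_windows` element: list of `low`,
#'   `high` (each `c(start, end)`, half-open, 0-based), `n_tr` and
#'   `tr_seconds`.
#' @export
epochs_to_tr <- function(pair, tr_seconds, lag_seconds = 0) {
  stopifnot(inherits(pair, "epoch_pair"))
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be positive")
  win <- function(w) c(floor((w[1L] + lag_seconds) / tr_seconds),
                       floor((w[2L] + lag_seconds) / tr_seconds))
  lo <- win(pair$low_window)
  hi <- win(pair$high_window)
  n_tr <- min(lo[2L] - lo[1L], hi[2L] - hi[1L])
  if (n_tr < 3L)
    stop("epoch windows map to ", n_tr, " volume(s); need >= 3 TRs")
  lo[2L] <- lo[1L] + n_tr
  hi[2L] <- hi[1L] + n_tr
  pair$tr_windows <- list(low = lo, high = hi, n_tr = n_tr,
                          tr_seconds = tr_seconds)
  pair
}
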