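#' Specification for a synthetic multi-subject cohort
#'
#' Defines the statistical structure the analysis assumes: a designated hub
#' node acting as a common cause whose coupling to every other node is
#' stronger in one condition than the other, network-shared background
#' variance, and a behavioral score coupled (with configurable slope and
#' noise) to each subject's planted low-minus-high coupling difference.
#' Defaults emulate the study design the package targets: 74 subjects, the
#' packaged 14-ROI two-network set, 44 volumes per condition at TR 3 s, hub
#' "vmPFC" with condition couplings 0.15 (low) vs 0.45 (high).
#'
#' @param n_subjects Number of subjects; default 74.
#' @param roiset An [roi_set]; default [default_roi_set()].
#' @param t_per_condition Volumes per condition; default 44.
#' @param tr_seconds Repetition time; default 3.
#' @param hub_label Hub ROI label; default `"vmPFC"`.
#' @param coupling_low,coupling_high Hub-to-node coupling per condition, in
#'   \[0, 1); defaults 0.15 and 0.45. Equal values give a null cohort.
#' @param shared_factor_sd SD of the per-network shared background factor's
#'   contribution; default 0.3.
#' @param noise_sd SD of node-private white noise; default 1.
#' @param subject_coupling_sd Between-subject SD of the coupling; default 0.1.
#' @param behavior_slope Slope linking the behavioral score to the subject's
#'   (low - high) coupling difference; negative (default -1) makes behavior
#'   correlate negatively with the (low - high) hub influence difference.
#' @param behavior_noise_sd SD of behavioral noise; default 0.2.
#' @param rate_hz Rating sampling rate; default 10.
#' @param scale_levels Rating scale degrees; default 21.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_subjects = 74L,
                        roiset = default_roi_set(),
                        t_per_condition = 44L,
                        tr_seconds = 3,
                        hub_label = "vmPFC",
                        coupling_low = 0.15,
                        coupling_high = 0.45,
                        shared_factor_sd = 0.3,
                        noise_sd = 1,
                        subject_coupling_sd = 0.1,
                        behavior_slope = -1,
                        behavior_noise_sd = 0.2,
                        rate_hz = 10,
                        scale_levels = 21L,
                        seed = 1L) {
  stopifnot(inherits(roiset, "roi_set"))
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (t_per_condition < length(roiset) + 2L)
    warning("t_per_condition below n_ROIs + 2; correlations will be unstable")
  if (!hub_label %in% roiset$labels)
    stop("hub_label '", hub_label, "' not in the ROI set")
  for (cc in c(coupling_low, coupling_high))
    if (cc < 0 || cc >= 1) stop("couplings must lie in [0, 1)")
  for (s in c(shared_factor_sd, noise_sd, subject_coupling_sd,
              behavior_noise_sd))
    if (!is.numeric(s) || s <= 0) stop("all sd parameters must be > 0")
  structure(list(n_subjects = as.integer(n_subjects), roiset = roiset,
                 t_per_condition = as.integer(t_per_condition),
                 tr_seconds = tr_seconds, hub_label = hub_label,
                 coupling_low = coupling_low, coupling_high = coupling_high,
                 shared_factor_sd = shared_factor_sd, noise_sd = noise_sd,
                 subject_coupling_sd = subject_coupling_sd,
                 behavior_slope = behavior_slope,
                 behavior_noise_sd = behavior_noise_sd,
                 rate_hz = rate_hz, scale_levels = as.integer(scale_levels),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a multi-subject two-condition cohort
#'
#' For each subject s and condition c the hub carries a unit-variance white
#' Gaussian signal h; every other node i receives
#' `x_i = beta_{s,c} * h + shared_factor_sd * f_net(i) + eps_i`, where
#' f_net is a white factor shared within the node's sub-network and eps_i is
#' node-private noise. `beta_{s,c}` is the condition coupling plus a
#' per-subject jitter (truncated to \[0.01, 0.9\]). The behavioral latent is
#' `b_s = behavior_slope * (beta_low - beta_high) + noise`; it drives the
#' high-plateau amplitude of the subject's rating trace (hence the rating
#' AUC) and the trait-anger score. Rating traces are low-then-high step
#' profiles spanning the concatenated two-condition run, with smoothed
#' per-subject jitter, so that the epoch search recovers the two condition
#' blocks.
#'
#' @param spec A [cohort_spec].
#' @return Object of class `depna_cohort`: `spec`, `roiset`, `subjects`
#'   (ids), `ts_low` / `ts_high` (named lists of [subject_timeseries]),
#'   `ratings` (named list of [rating_trace]), `behavior` (data frame:
#'   `subject_id`, `anger_auc`, `trait_anger`, `reappraisal`,
#'   `suppression`), `coupling` (data frame: `subject_id`, `beta_low`,
#'   `beta_high`, `latent`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rs <- spec$roiset
  n <- spec$n_subjects
  tt <- spec$t_per_condition
  labels <- rs$labels
  hub <- match(spec$hub_label, labels)
  nets <- unique(rs$network)
  ids <- sprintf("sub%03d", seq_len(n))

  beta_low <- pmin(0.9, pmax(0.01,
    spec$coupling_low + stats::rnorm(n, 0, spec$subject_coupling_sd)))
  beta_high <- pmin(0.9, pmax(0.01,
    spec$coupling_high + stats::rnorm(n, 0, spec$subject_coupling_sd)))
  latent <- spec$behavior_slope * (beta_low - beta_high) +
    stats::rnorm(n, 0, spec$behavior_noise_sd)
  z_latent <- if (stats::sd(latent) > 0)
    (latent - mean(latent)) / stats::sd(latent) else rep(0, n)

  one_condition <- function(beta) {
    h <- stats::rnorm(tt)
    f <- sapply(nets, function(dummy) stats::rnorm(tt))
    colnames(f) <- nets
    x <- matrix(0, tt, length(labels), dimnames = list(NULL, labels))
    for (i in seq_along(labels)) {
      if (i == hub) {
        x[, i] <- h
      } else {
        x[, i] <- beta * h + spec$shared_factor_sd * f[, rs$network[i]] +
          stats::rnorm(tt, 0, spec$noise_sd)
      }
    }
    x
  }

  ts_low <- vector("list", n); ts_high <- vector("list", n)
  ratings <- vector("list", n)
  dur_s <- 2 * tt * spec$tr_seconds
  n_samp <- as.integer(round(dur_s * spec$rate_hz))
  half <- n_samp %/% 2L
  top <- spec$scale_levels - 1
  for (s in seq_len(n)) {
    ts_low[[s]] <- subject_timeseries(ids[s], one_condition(beta_low[s]),
                                      spec$tr_seconds)
    ts_high[[s]] <- subject_timeseries(ids[s], one_condition(beta_high[s]),
                                       spec$tr_seconds)
    lo_level <- 2 + stats::rnorm(1, 0, 0.5)
    hi_level <- 0.6 * top + 0.15 * top * z_latent[s] + stats::rnorm(1, 0, 0.5)
    base <- c(rep(lo_level, half), rep(hi_level, n_samp - half))
    jitter <- stats::filter(stats::rnorm(n_samp, 0, 0.8), rep(1 / 5, 5),
                            sides = 2)
    jitter[is.na(jitter)] <- 0
    samples <- pmin(top, pmax(0, base + as.numeric(jitter)))
    ratings[[s]] <- rating_trace(ids[s], samples, spec$rate_hz,
                                 spec$scale_levels)
  }
  names(ts_low) <- names(ts_high) <- names(ratings) <- ids

  behavior <- data.frame(
    subject_id = ids,
    anger_auc = vapply(ratings, rating_auc, numeric(1)),
    trait_anger = pmin(40, pmax(10, round(24 + 6 * z_latent +
                                            stats::rnorm(n, 0, 2)))),
    reappraisal = pmin(7, pmax(1, round(stats::rnorm(n, 4.5, 1), 1))),
    suppression = pmin(7, pmax(1, round(stats::rnorm(n, 3.5, 1), 1))),
    stringsAsFactors = FALSE)
  rownames(behavior) <- NULL

  structure(list(spec = spec, roiset = rs, subjects = ids,
                 ts_low = ts_low, ts_high = ts_high, ratings = ratings,
                 behavior = behavior,
                 coupling = data.frame(subject_id = ids,
                                       beta_low = beta_low,
                                       beta_high = beta_high,
                                       latent = latent,
                                       stringsAsFactors = FALSE)),
            class = "depna_cohort")
}

#' @export
print.depna_cohort <- function(x, ...) {
  cat("depna_cohort: ", length(x$subjects), " subjects, ",
      length(x$roiset), " ROIs, ", x$spec$t_per_condition,
      " TRs/condition, hub '", x$spec$hub_label, "' (",
      x$spec$coupling_low, " -> ", x$spec$coupling_high, ")\n", sep = "")
  invisible(x)
}

#' Pool of independent null node time series
#'
#' I.i.d. standard-Gaussian candidate node signals, for drawing size-matched
#' random networks in [random_network_stats()] in place of atlas-based
#' gray-matter sampling.
#'
#' @param t Time points per node.
#' @param n_pool Number of candidate nodes.
#' @param seed Integer seed.
#' @return A `t` x `n_pool` matrix with columns `pool1`, `pool2`, ...
#' @export
simulate_null_pool <- function(t, n_pool, seed = 1L) {
  if (t < 3L) stop("need at least 3 time points")
  if (n_pool < 1L) stop("need at least one pool node")
  set.seed(as.integer(seed))
  m <- matrix(stats::rnorm(t * n_pool), nrow = t)
  colnames(m) <- paste0("pool", seq_len(n_pool))
  m
}
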