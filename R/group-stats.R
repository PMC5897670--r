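#' Paired condition contrast of per-node influence scores
#'
#' Two-tailed paired t-test per node on subjects x nodes score matrices from
#' the two conditions, df = n - 1, with Benjamini-Hochberg adjusted q-values
#' over the node family. Zero-variance difference vectors are reported with
#' an explicit `degenerate` flag (t = +/-Inf, p = 0 when the mean difference
#' is nonzero; t = 0, p = 1 when every difference is zero) instead of NaN.
#'
#' @param scores_low,scores_high Subjects x nodes matrices with matching
#'   subject rownames (order may differ) and node colnames.
#' @param m Number of tests for the FDR correction; defaults to the node
#'   count.
#' @return Data frame: `node`, `mean_low`, `sd_low`, `mean_high`, `sd_high`,
#'   `t`, `df`, `p`, `q`, `direction` (sign of high - low), `degenerate`.
#' @export
paired_condition_ttest <- function(scores_low, scores_high, m = NULL) {
  scores_low <- as.matrix(scores_low)
  scores_high <- as.matrix(scores_high)
  if (!identical(colnames(scores_low), colnames(scores_high)))
    stop("node columns differ between conditions")
  ids_low <- rownames(scores_low); ids_high <- rownames(scores_high)
  if (!is.null(ids_low) && !is.null(ids_high)) {
    if (!setequal(ids_low, ids_high))
      stop("subject sets differ between conditions")
    scores_high <- scores_high[ids_low, , drop = FALSE]
  } else if (nrow(scores_low) != nrow(scores_high)) {
    stop("subject counts differ between conditions")
  }
  n <- nrow(scores_low)
  if (n < 3L) stop("paired t-test needs n >= 3 subjects")
  if (is.null(m)) m <- ncol(scores_low)
  res <- lapply(seq_len(ncol(scores_low)), function(jj) {
    lo <- scores_low[, jj]; hi <- scores_high[, jj]
    tt <- .paired_t(hi, lo)
    data.frame(node = colnames(scores_low)[jj],
               mean_low = mean(lo), sd_low = stats::sd(lo),
               mean_high = mean(hi), sd_high = stats::sd(hi),
               t = tt$t, df = tt$df, p = tt$p,
               direction = sign(mean(hi) - mean(lo)),
               degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # degenerate zero-variance nodes report p = 0; floor for the adjustment
  out$q <- bh_fdr(pmax(out$p, .Machine$double.xmin), m = m)
  out[, c("node", "mean_low", "sd_low", "mean_high", "sd_high",
          "t", "df", "p", "q", "direction", "degenerate")]
}

# Closed-form two-tailed paired t with explicit degenerate handling.
.paired_t <- function(hi, lo) {
  d <- hi - lo
  n <- length(d)
  s <- stats::sd(d)
  # a difference vector constant up to floating-point error is degenerate
  if (s == 0 || s < 1e-12 * abs(mean(d))) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1L),
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over a family of `m` tests (delegating to
#' [stats::p.adjust()]); `m` may exceed the number of p-values supplied when
#' the remaining family members are not reported.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param m Family size; defaults to `length(pvals)`.
#' @return Vector of adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (m < length(pvals)) stop("family size m must be >= length(pvals)")
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Edgewise condition-contrast graph
#'
#' Runs a paired t-test across subjects on every off-diagonal dependency
#' entry D(i, j) and keeps, as directed edges j -> i (the direction of
#' influence), the entries differing between conditions at `p < alpha`.
#' Node scores are the mean condition difference (high - low) of the
#' influencing degree.
#'
#' @param dep_low,dep_high N x N x subjects arrays of dependency matrices
#'   (node dimnames required on the first two margins), aligned by subject.
#' @param alpha Edge retention threshold; default 0.05.
#' @return Object of class `edge_contrast_graph`: `nodes` (data frame
#'   `label`, `score`), `edges` (data frame `from`, `to`, `t`, `p`,
#'   `direction`), `alpha`, and `t_matrix` (full N x N matrix of edgewise t
#'   values, for export).
#' @export
edge_contrast_graph <- function(dep_low, dep_high, alpha = 0.05) {
  if (!identical(dim(dep_low), dim(dep_high)))
    stop("dependency stacks are not aligned")
  if (!identical(dimnames(dep_low)[1:2], dimnames(dep_high)[1:2]))
    stop("dependency stacks have mismatched node labels")
  if (!is.null(dimnames(dep_low)[[3L]]) &&
      !identical(dimnames(dep_low)[[3L]], dimnames(dep_high)[[3L]]))
    stop("dependency stacks have mismatched subjects")
  n <- dim(dep_low)[1L]
  labels <- dimnames(dep_low)[[1L]]
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  deg_lo <- apply(dep_low, 3L, colSums)   # nodes x subjects
  deg_hi <- apply(dep_high, 3L, colSums)
  nodes <- data.frame(label = labels,
                      score = rowMeans(deg_hi) - rowMeans(deg_lo),
                      stringsAsFactors = FALSE)
  edges <- list()
  t_matrix <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tt <- .paired_t(dep_high[i, j, ], dep_low[i, j, ])
    t_matrix[i, j] <- if (is.finite(tt$t)) tt$t else sign(tt$t) * 1e6
    if (tt$p < alpha)
      edges[[length(edges) + 1L]] <- data.frame(
        from = labels[j], to = labels[i], t = tt$t, p = tt$p,
        direction = sign(tt$t), stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), t = numeric(),
               p = numeric(), direction = numeric(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 t_matrix = t_matrix),
            class = "edge_contrast_graph")
}

#' @export
print.edge_contrast_graph <- function(x, ...) {
  cat("edge_contrast_graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges at p < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Correlate influence condition differences with behavior
#'
#' Pearson correlation between a per-subject influence difference (by the
#' package's convention: low minus high) and a behavioral measure, after
#' listwise deletion of missing values and exclusion of subjects deviating
#' from the mean by more than `exclusion_sd` standard deviations on either
#' variable (computed on the complete pairs).
#'
#' @param delta_scores Named (or positionally aligned) numeric vector of
#'   per-subject influence differences.
#' @param behavior Numeric vector of the behavioral measure; `NA` allowed.
#' @param exclusion_sd Outlier threshold in standard deviations; default 3.
#' @return List: `r`, `p` (two-tailed), `n_used`, `excluded` (indices
#'   removed by the SD rule).
#' @export
behavior_correlation <- function(delta_scores, behavior, exclusion_sd = 3) {
  if (length(delta_scores) != length(behavior))
    stop("delta_scores and behavior must have the same length")
  ok <- is.finite(delta_scores) & is.finite(behavior)
  x <- delta_scores[ok]; y <- behavior[ok]
  out_x <- abs(x - mean(x)) > exclusion_sd * stats::sd(x)
  out_y <- abs(y - mean(y)) > exclusion_sd * stats::sd(y)
  drop <- out_x | out_y
  excluded <- which(ok)[drop]
  x <- x[!drop]; y <- y[!drop]
  if (length(x) < 4L)
    stop("fewer than 4 complete subject pairs after exclusion")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = length(x),
       excluded = excluded)
}

#' Random-network specificity bootstrap
#'
#' Compares an observed statistic (a paired-t value or a behavior
#' correlation) with the same statistic recomputed on size-matched random
#' networks, yielding an empirical p-value with add-one smoothing:
#' `p = (#extreme + 1) / (k + 1)`. By default "extreme" means at least as
#' extreme as the observed value in the observed direction (random >=
#' observed when the observed statistic is positive, random <= observed when
#' negative). `literal_eq5 = TRUE` instead counts random values <= observed
#' regardless of sign, reproducing the formula as originally printed.
#'
#' @param observed Observed scalar statistic.
#' @param random_stats Numeric vector of k statistics from random networks
#'   (e.g. via [random_network_stats()]).
#' @param mode `"tstat"` or `"correlation"`; both use the sign of `observed`
#'   to orient extremeness, the distinction is recorded in the output.
#' @param literal_eq5 Use the literal smaller-than-observed count.
#' @return List: `p`, `k`, `observed`, `mode`, `direction`.
#' @export
specificity_bootstrap <- function(observed, random_stats,
                                  mode = c("tstat", "correlation"),
                                  literal_eq5 = FALSE) {
  mode <- match.arg(mode)
  k <- length(random_stats)
  if (k < 1L) stop("need at least one random-network statistic (k >= 1)")
  if (k < 100L)
    warning("k = ", k, " random networks; empirical p is coarse below 100")
  if (!is.finite(observed)) stop("observed statistic must be finite")
  direction <- if (observed >= 0) 1 else -1
  count <- if (literal_eq5) {
    sum(random_stats <= observed)
  } else if (direction > 0) {
    sum(random_stats >= observed)
  } else {
    sum(random_stats <= observed)
  }
  list(p = (count + 1) / (k + 1), k = k, observed = observed, mode = mode,
       direction = direction)
}

#' Statistics of random node networks drawn from a pool
#'
#' Draws `k` random node subsets of size `n_nodes` from a candidate pool and
#' applies a user statistic to each, producing the background distribution
#' for [specificity_bootstrap()]. The pool stands in for the random
#' gray-matter region sampling of the original design: any source of
#' candidate node time series (e.g. [simulate_null_pool()]) can be used.
#'
#' @param pool_size Number of candidate nodes available.
#' @param n_nodes Network size to draw (<= `pool_size`).
#' @param k Number of random networks.
#' @param stat_fn Function receiving an integer vector of pool indices and
#'   returning a scalar statistic.
#' @return Numeric vector of k statistics.
#' @export
random_network_stats <- function(pool_size, n_nodes, k, stat_fn) {
  if (n_nodes > pool_size)
    stop("pool of ", pool_size, " candidates is smaller than the network (",
         n_nodes, ")")
  vapply(seq_len(k), function(b)
    stat_fn(sample.int(pool_size, n_nodes)), numeric(1))
}
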