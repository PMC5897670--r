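#' Dependency network analysis: correlation-based node influence
#'
#' The core of the package decomposes pairwise Pearson correlations with
#' third-node partial correlations. For nodes i, k and a conditioning node j,
#'
#' \deqn{PC(i,k|j) = \frac{C(i,k) - C(i,j) C(k,j)}
#'                        {\sqrt{[1 - C^2(i,j)][1 - C^2(k,j)]}}}
#'
#' and the influence of j on the i-k connection is
#' \eqn{d(i,k|j) = C(i,k) - PC(i,k|j)}, floored at zero so that positive and
#' negative contributions are never summed against each other. Averaging
#' d(i,k|j) over k (excluding j) gives the dependency matrix entry D(i,j) --
#' the average influence of node j on node i's correlations -- and summing
#' D(i,j) over i gives node j's "influencing degree", its system-level
#' out-influence. The matrix D is non-negative and in general asymmetric.
#'
#' @name depna-core
NULL

#' Correlation matrix container
#'
#' @param values Symmetric N x N numeric matrix.
#' @param transform `"raw_r"` (Pearson r, unit diagonal) or `"fisher_z"`
#'   (entrywise atanh of off-diagonal r).
#' @return Object of class `depna_corr` with elements `values` and
#'   `transform`.
#' @export
correlation_matrix <- function(values, transform = c("raw_r", "fisher_z")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("correlation matrix must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stop("correlation matrix must be symmetric (tolerance 1e-12)")
  values <- (values + t(values)) / 2
  if (transform == "raw_r") {
    if (max(abs(diag(values) - 1)) > 1e-12)
      stop("raw_r correlation matrix must have unit diagonal")
    if (max(abs(values)) > 1 + 1e-12)
      stop("raw_r correlation entries must lie in [-1, 1]")
  }
  if (is.null(colnames(values)))
    dimnames(values) <- list(.col_labels(values), .col_labels(values))
  structure(list(values = values, transform = transform),
            class = "depna_corr")
}

#' @export
print.depna_corr <- function(x, ...) {
  cat("depna_corr: ", nrow(x$values), " x ", ncol(x$values),
      " (", x$transform, ")\n", sep = "")
  invisible(x)
}

#' Pairwise Pearson correlations of ROI time series
#'
#' @param ts A [subject_timeseries] or plain T x N matrix (rows = time).
#' @return A [correlation_matrix] with `transform = "raw_r"`.
#' @export
pearson_correlations <- function(ts) {
  m <- .ts_matrix(ts)
  if (nrow(m) < 3L)
    stop("need at least 3 time points for a correlation matrix")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI column(s): ",
         paste(.col_labels(m)[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  correlation_matrix(r, "raw_r")
}

#' Fisher z-transform a correlation matrix
#'
#' Applies atanh entrywise off the diagonal. Off-diagonal entries with
#' |r| >= 1 are clipped to +/-(1 - 1e-7) with a warning so the transform
#' stays finite. The diagonal is set to 0 (atanh(1) is infinite and the
#' diagonal never enters any influence computation).
#'
#' @param c A [correlation_matrix] with `transform = "raw_r"`.
#' @return A [correlation_matrix] with `transform = "fisher_z"`.
#' @export
fisher_z <- function(c) {
  stopifnot(inherits(c, "depna_corr"))
  if (c$transform != "raw_r")
    stop("correlation matrix is already Fisher z-transformed")
  v <- c$values
  clip <- 1 - 1e-7
  off <- row(v) != col(v)
  if (any(abs(v[off]) >= clip)) {
    warning("off-diagonal |r| >= 1 - 1e-7 clipped before Fisher z")
    v[off & v >= clip] <- clip
    v[off & v <= -clip] <- -clip
  }
  z <- atanh(v * off)       # off-diagonal atanh; diagonal -> atanh(0) = 0
  dimnames(z) <- dimnames(v)
  structure(list(values = z, transform = "fisher_z"), class = "depna_corr")
}

# Partial-correlation matrix PC(., .|j) for one conditioning node j.
# `dfloor`: if non-NULL, denominator arguments 1 - C^2 are floored at this
# value (used on the fisher_z path where |C| can exceed 1).
.pc_matrix <- function(v, j, dfloor = NULL, labels = NULL) {
  cj <- v[, j]
  den <- 1 - cj * cj
  if (is.null(dfloor)) {
    bad <- which(den <= 0)
    bad <- setdiff(bad, j)
    if (length(bad))
      stop("degenerate conditioning: |C(", labels[bad[1L]], ", ", labels[j],
           ")| = 1")
  } else {
    den <- pmax(den, dfloor)
  }
  (v - outer(cj, cj)) / sqrt(outer(den, den))
}

.corr_labels <- function(c) colnames(c$values)

#' Partial correlation of two nodes given a third
#'
#' @param c A [correlation_matrix]. The default analysis applies the formula
#'   to raw Pearson r, for which it is the exact correlation of the two
#'   nodes' residuals after regressing out the conditioning node. On a
#'   `fisher_z` matrix the same arithmetic is applied with denominator
#'   arguments floored at 1e-12 (and a warning), reproducing the transformed
#'   variant verbatim.
#' @param i,k Node indices (or labels) whose correlation is conditioned.
#' @param j Conditioning node index (or label); distinct from `i` and `k`.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(c, i, k, j) {
  stopifnot(inherits(c, "depna_corr"))
  idx <- .resolve_nodes(c, c(i, k, j))
  if (anyDuplicated(idx)) stop("i, k, j must be distinct nodes")
  v <- c$values
  labels <- .corr_labels(c)
  if (c$transform == "fisher_z") {
    warning("applying the partial-correlation formula to Fisher-z values; ",
            "denominator arguments floored at 1e-12")
    pc <- .pc_matrix(v, idx[3L], dfloor = 1e-12, labels = labels)
  } else {
    pc <- .pc_matrix(v, idx[3L], labels = labels)
  }
  pc[idx[1L], idx[2L]]
}

.resolve_nodes <- function(c, nodes) {
  labels <- .corr_labels(c)
  if (is.character(nodes)) {
    idx <- match(nodes, labels)
    if (anyNA(idx)) stop("unknown node label(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1L | idx > nrow(c$values))) stop("node index out of range")
    idx
  }
}

#' Influence of a third node on a pairwise correlation
#'
#' `d(i,k|j) = max(0, C(i,k) - PC(i,k|j))`: the part of the i-k correlation
#' attributable to j, floored at zero. Symmetric in `i` and `k`.
#'
#' @inheritParams partial_correlation
#' @return Non-negative scalar.
#' @export
influence_d <- function(c, i, k, j) {
  idx <- .resolve_nodes(c, c(i, k))
  max(0, c$values[idx[1L], idx[2L]] - partial_correlation(c, i, k, j))
}

#' The dependency matrix D
#'
#' `D(i,j)` is the average influence of node j on node i's correlations:
#' `D(i,j) = (1/(N-1)) * sum_{k != j} d(i,k|j)`. The k = i term is included
#' in the sum as written but contributes exactly 0 (a correlation of a node
#' with itself cannot be mediated). The diagonal is 0 and the matrix is
#' non-negative and asymmetric in general.
#'
#' @param c A [correlation_matrix] (N >= 3 nodes).
#' @param condition_tag Optional string recorded with the result (e.g. the
#'   task condition the epoch came from).
#' @param degenerate Policy for off-diagonal |r| = 1 on the raw path:
#'   `"error"` (default) or `"clip"` (denominator arguments floored at
#'   1e-12).
#' @return Object of class `depna_dependency` with elements `values`
#'   (labelled N x N matrix) and `condition_tag`.
#' @export
dependency_matrix <- function(c, condition_tag = "",
                              degenerate = c("error", "clip")) {
  stopifnot(inherits(c, "depna_corr"))
  degenerate <- match.arg(degenerate)
  v <- c$values
  n <- nrow(v)
  if (n < 3L) stop("dependency matrix needs N >= 3 nodes")
  labels <- .corr_labels(c)
  dfloor <- if (c$transform == "fisher_z" || degenerate == "clip") 1e-12 else NULL
  if (c$transform == "fisher_z")
    warning("computing dependencies from Fisher-z values; ",
            "denominator arguments floored at 1e-12")
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (j in seq_len(n)) {
    pc <- .pc_matrix(v, j, dfloor = dfloor, labels = labels)
    dj <- v - pc
    dj[dj < 0] <- 0        # negative influences reset to zero
    diag(dj) <- 0          # k = i term: identically zero
    dj[, j] <- 0           # k = j excluded from the sum
    dj[j, ] <- 0           # i = j row unused (diagonal of D forced to 0)
    D[, j] <- rowSums(dj) / (n - 1)
  }
  diag(D) <- 0
  structure(list(values = D, condition_tag = as.character(condition_tag)),
            class = "depna_dependency")
}

#' @export
print.depna_dependency <- function(x, ...) {
  cat("depna_dependency: ", nrow(x$values), " x ", ncol(x$values),
      if (nzchar(x$condition_tag)) paste0(" [", x$condition_tag, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Influence profile container
#'
#' Per-node influence scores under one aggregation scheme.
#'
#' @param scheme One of `"global_degree"`, `"intra"`, `"inter_within_other"`,
#'   `"inter_between"`.
#' @param scores Named non-negative numeric vector (names = source nodes).
#' @param source_network,target_network Optional network tags.
#' @param normalization `"mean"` or `"sum"` over contributing (i, k) pairs
#'   (only meaningful for the inter-network schemes).
#' @return Object of class `influence_profile`.
#' @export
influence_profile <- function(scheme, scores, source_network = NULL,
                              target_network = NULL, normalization = NA_character_) {
  scheme <- match.arg(scheme, c("global_degree", "intra",
                                "inter_within_other", "inter_between"))
  if (is.null(names(scores)) || anyNA(names(scores)))
    stop("influence scores must be named by node label")
  if (any(scores < -1e-12))
    stop("influence scores must be non-negative")
  scores <- pmax(scores, 0)
  structure(list(scheme = scheme, scores = scores,
                 source_network = source_network,
                 target_network = target_network,
                 normalization = normalization),
            class = "influence_profile")
}

#' @export
print.influence_profile <- function(x, ...) {
  cat("influence_profile [", x$scheme, "]",
      if (!is.null(x$source_network)) paste0(" ", x$source_network),
      if (!is.null(x$target_network)) paste0(" -> ", x$target_network),
      "\n", sep = "")
  print(round(x$scores, 4))
  invisible(x)
}

#' Influencing degree of every node
#'
#' Node j's influencing degree is `sum_{i != j} D(i,j)`: the column sum of
#' the dependency matrix, ranking nodes by their out-influence on all other
#' connections in the network.
#'
#' @param D A `depna_dependency` object (from [dependency_matrix()]).
#' @return An [influence_profile] with scheme `"global_degree"`.
#' @export
influencing_degree <- function(D) {
  stopifnot(inherits(D, "depna_dependency"))
  influence_profile("global_degree", colSums(D$values))
}

.subnet_idx <- function(c, roiset, net) {
  labels <- .corr_labels(c)
  if (!setequal(labels, roiset$labels) || !all(labels == roiset$labels))
    stop("correlation matrix labels do not match the ROI set order")
  if (is.null(net) || !net %in% roiset$network)
    stop("unknown network tag: ", if (is.null(net)) "NULL" else net)
  which(roiset$network == net)
}

#' Intra-network influence
#'
#' Each member node's influence on connections inside its own sub-network.
#' By default the sub-network is treated as a self-contained system: the
#' correlation sub-matrix is extracted and the dependency matrix and
#' influencing degree are recomputed on it alone (conditioning sums run only
#' over sub-network members). `mode = "masked_full"` instead masks the
#' full-network dependency matrix and sums its sub-network block column-wise,
#' retaining full-network conditioning.
#'
#' @param c A [correlation_matrix] over the full ROI set.
#' @param roiset The [roi_set] matching `c`'s node order.
#' @param net Sub-network tag (>= 3 members).
#' @param mode `"subnetwork"` (default) or `"masked_full"`.
#' @return An [influence_profile] with scheme `"intra"` over the members.
#' @export
intra_network_influence <- function(c, roiset, net,
                                    mode = c("subnetwork", "masked_full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(c, "depna_corr"))
  idx <- .subnet_idx(c, roiset, net)
  if (length(idx) < 3L)
    stop("intra-network influence needs >= 3 members in '", net, "'")
  if (mode == "subnetwork") {
    sub <- structure(list(values = c$values[idx, idx, drop = FALSE],
                          transform = c$transform), class = "depna_corr")
    scores <- colSums(dependency_matrix(sub)$values)
  } else {
    D <- dependency_matrix(c)$values
    block <- D[idx, idx, drop = FALSE]
    diag(block) <- 0
    scores <- colSums(block)
  }
  influence_profile("intra", scores, source_network = net,
                    target_network = net)
}

# d(., .|j) matrix for node j of a raw/fisher correlation matrix.
.d_matrix <- function(c, j) {
  labels <- .corr_labels(c)
  dfloor <- if (c$transform == "fisher_z") 1e-12 else NULL
  pc <- .pc_matrix(c$values, j, dfloor = dfloor, labels = labels)
  d <- c$values - pc
  d[d < 0] <- 0
  diag(d) <- 0
  d[, j] <- 0
  d[j, ] <- 0
  d
}

#' Inter-network influence on connections within the other network
#'
#' For each source-network node j, aggregates `d(i,k|j)` over unordered node
#' pairs \{i, k\} lying entirely inside the target network: how much j
#' explains of the target network's internal connectivity.
#'
#' @inheritParams intra_network_influence
#' @param source_net,target_net Distinct network tags; the target needs
#'   >= 2 members.
#' @param normalization `"mean"` (default; per contributing pair) or `"sum"`.
#' @return An [influence_profile] with scheme `"inter_within_other"`.
#' @export
inter_network_influence_within <- function(c, roiset, source_net, target_net,
                                           normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(c, "depna_corr"))
  if (identical(source_net, target_net))
    stop("source and target networks must differ")
  src <- .subnet_idx(c, roiset, source_net)
  tgt <- .subnet_idx(c, roiset, target_net)
  if (length(tgt) < 2L)
    stop("target network '", target_net, "' needs >= 2 members")
  scores <- vapply(src, function(j) {
    d <- .d_matrix(c, j)[tgt, tgt, drop = FALSE]
    vals <- d[upper.tri(d)]
    if (normalization == "mean") mean(vals) else sum(vals)
  }, numeric(1))
  names(scores) <- roiset$labels[src]
  influence_profile("inter_within_other", scores,
                    source_network = source_net, target_network = target_net,
                    normalization = normalization)
}

#' Inter-network influence on connections between the two networks
#'
#' For each source-network node j, aggregates `d(i,k|j)` over pairs that
#' straddle the two networks: i in the target network, k in the source
#' network excluding j itself.
#'
#' @inheritParams inter_network_influence_within
#' @return An [influence_profile] with scheme `"inter_between"`.
#' @export
inter_network_influence_between <- function(c, roiset, source_net, target_net,
                                            normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(c, "depna_corr"))
  if (identical(source_net, target_net))
    stop("source and target networks must differ")
  src <- .subnet_idx(c, roiset, source_net)
  tgt <- .subnet_idx(c, roiset, target_net)
  if (length(src) < 2L)
    stop("source network '", source_net,
         "' needs >= 2 members (j is excluded from its own pair slots)")
  scores <- vapply(src, function(j) {
    d <- .d_matrix(c, j)[tgt, setdiff(src, j), drop = FALSE]
    if (normalization == "mean") mean(d) else sum(d)
  }, numeric(1))
  names(scores) <- roiset$labels[src]
  influence_profile("inter_between", scores,
                    source_network = source_net, target_network = target_net,
                    normalization = normalization)
}

#' Total inter-network influence
#'
#' Sum of one network's per-node inter-network influences on the other: a
#' single scalar summarizing how strongly the source network as a whole
#' drives the target network's connectivity.
#'
#' @param profile An [influence_profile] with an inter-network scheme.
#' @return Scalar sum of the profile's scores.
#' @export
total_inter_network_influence <- function(profile) {
  stopifnot(inherits(profile, "influence_profile"))
  if (!profile$scheme %in% c("inter_within_other", "inter_between"))
    stop("total inter-network influence is defined for inter-network ",
         "profiles only (got scheme '", profile$scheme, "')")
  sum(profile$scores)
}

#' Per-subject influence scores for a whole cohort
#'
#' Runs Pearson correlation + the requested influence aggregation for every
#' subject in a list and stacks the resulting scores into a subjects x nodes
#' matrix, ready for [paired_condition_ttest()].
#'
#' @param ts_list Named list of [subject_timeseries] (one condition).
#' @param roiset The [roi_set] fixing node order.
#' @param scheme Aggregation scheme (see [influence_profile]).
#' @param source_net,target_net Network tags for the intra / inter schemes.
#' @param normalization Pair normalization for the inter schemes.
#' @param transform `"raw_r"` (default) or `"fisher_z"` applied before the
#'   influence computation.
#' @param intra_mode Passed to [intra_network_influence()].
#' @return Numeric matrix, rownames = subject ids, colnames = source nodes.
#' @export
cohort_influence <- function(ts_list, roiset,
                             scheme = c("global_degree", "intra",
                                        "inter_within_other", "inter_between"),
                             source_net = NULL, target_net = NULL,
                             normalization = "mean",
                             transform = c("raw_r", "fisher_z"),
                             intra_mode = "subnetwork") {
  scheme <- match.arg(scheme)
  transform <- match.arg(transform)
  rows <- lapply(ts_list, function(ts) {
    c <- pearson_correlations(ts)
    if (transform == "fisher_z")
      c <- suppressWarnings(fisher_z(c))
    prof <- switch(scheme,
      global_degree = influencing_degree(suppressWarnings(dependency_matrix(c))),
      intra = intra_network_influence(c, roiset, source_net, mode = intra_mode),
      inter_within_other = inter_network_influence_within(
        c, roiset, source_net, target_net, normalization),
      inter_between = inter_network_influence_between(
        c, roiset, source_net, target_net, normalization))
    prof$scores
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(ts_list, function(ts)
    if (inherits(ts, "subject_timeseries")) ts$subject_id else "", character(1))
  out
}
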