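# Independent brute-force oracles: literal loop implementations of the
# partial-correlation influence decomposition, kept deliberately separate
# from the package's vectorized code paths.

oracle_pc <- function(C, i, k, j) {
  (C[i, k] - C[i, j] * C[k, j]) /
    sqrt((1 - C[i, j]^2) * (1 - C[k, j]^2))
}

oracle_d <- function(C, i, k, j) {
  max(0, C[i, k] - oracle_pc(C, i, k, j))
}

oracle_dependency <- function(C) {
  n <- nrow(C)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    acc <- 0
    for (k in seq_len(n)) {
      if (k == j) next
      acc <- acc + oracle_d(C, i, k, j)   # k = i term is identically 0
    }
    D[i, j] <- acc / (n - 1)
  }
  dimnames(D) <- dimnames(C)
  D
}

oracle_degree <- function(D) {
  n <- nrow(D)
  vapply(seq_len(n), function(j) sum(D[-j, j]), numeric(1))
}

oracle_intra <- function(C, idx) {
  oracle_degree(oracle_dependency(C[idx, idx, drop = FALSE]))
}

oracle_inter_within <- function(C, src, tgt, normalization = "mean") {
  vapply(src, function(j) {
    vals <- c()
    for (a in seq_along(tgt)) for (b in seq_along(tgt)) {
      if (a >= b) next
      vals <- c(vals, oracle_d(C, tgt[a], tgt[b], j))
    }
    if (normalization == "mean") mean(vals) else sum(vals)
  }, numeric(1))
}

oracle_inter_between <- function(C, src, tgt, normalization = "mean") {
  vapply(src, function(j) {
    vals <- c()
    for (i in tgt) for (k in setdiff(src, j)) {
      vals <- c(vals, oracle_d(C, i, k, j))
    }
    if (normalization == "mean") mean(vals) else sum(vals)
  }, numeric(1))
}

# Residual-regression partial correlation: correlate the residuals of
# columns i and k after least-squares removal of column j.
residual_pc <- function(X, i, k, j) {
  ri <- stats::residuals(stats::lm(X[, i] ~ X[, j]))
  rk <- stats::residuals(stats::lm(X[, k] ~ X[, j]))
  stats::cor(ri, rk)
}

# Random well-conditioned correlation matrix from random Gaussian data.
random_corr <- function(n, t = 4 * n + 20) {
  r <- stats::cor(matrix(stats::rnorm(t * n), ncol = n))
  colnames(r) <- rownames(r) <- paste0("n", seq_len(n))
  correlation_matrix(r, "raw_r")
}

# Expected (noise-free) correlation matrix of the hub model: node `hub`
# carries a unit-variance signal, every other node is alpha * hub + unit
# noise.
hub_model_corr <- function(n, hub = 1L, alpha = 0.5) {
  S <- matrix(alpha^2, n, n)
  diag(S) <- alpha^2 + 1
  S[hub, ] <- alpha
  S[, hub] <- alpha
  S[hub, hub] <- 1
  r <- stats::cov2cor(S)
  colnames(r) <- rownames(r) <- paste0("n", seq_len(n))
  correlation_matrix(r, "raw_r")
}

# Simulated hub-model data matrix (one subject, one condition).
hub_model_data <- function(t, n, hub = 1L, alpha = 0.5) {
  h <- stats::rnorm(t)
  x <- matrix(stats::rnorm(t * n), t, n)
  x <- x + alpha * outer(h, rep(1, n))
  x[, hub] <- h
  colnames(x) <- paste0("n", seq_len(n))
  x
}

# Cohort of i.i.d. Gaussian subjects for null calibration.
iid_cohort <- function(n_subjects, n_nodes, t) {
  ids <- sprintf("s%03d", seq_len(n_subjects))
  out <- lapply(ids, function(id)
    subject_timeseries(id, matrix(stats::rnorm(t * n_nodes), t,
                                  dimnames = list(NULL,
                                                  paste0("n", seq_len(n_nodes)))),
                       3))
  names(out) <- ids
  out
}

# Small two-network ROI set used across tests.
toy_roiset <- function(n_rea = 3L, n_reg = 4L) {
  roi_set(paste0("n", seq_len(n_rea + n_reg)),
          c(rep("reactivity", n_rea), rep("regulation", n_reg)))
}
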