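test_that("Pearson correlations: perfect, anti- and near-zero correlation", {
  set.seed(11)
  x <- rnorm(200)
  m <- cbind(a = x, b = x, c = -x, d = rnorm(200))
  cm <- pearson_correlations(m)
  expect_equal(cm$values["a", "b"], 1)
  expect_equal(cm$values["a", "c"], -1)
  expect_true(all(abs(cm$values) <= 1))
  expect_equal(diag(cm$values), c(a = 1, b = 1, c = 1, d = 1))
  expect_true(max(abs(cm$values - t(cm$values))) < 1e-15)

  set.seed(12)
  big <- matrix(rnorm(10000 * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  expect_lt(abs(pearson_correlations(big)$values["u", "v"]), 0.05)
})

test_that("Pearson correlations reject constant columns and short series", {
  m <- cbind(a = rnorm(10), flatroi = rep(1, 10))
  expect_error(pearson_correlations(m), "flatroi")
  expect_error(pearson_correlations(matrix(rnorm(4), 2)), "3 time points")
})

test_that("Fisher z transform matches atanh and guards its domain", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  z <- fisher_z(correlation_matrix(r))
  expect_equal(z$transform, "fisher_z")
  expect_equal(z$values["a", "b"], atanh(0.5))
  expect_equal(z$values["a", "b"], 0.5 * log(3))
  expect_equal(z$values["a", "c"], 0)
  expect_equal(z$values["b", "c"], atanh(-0.3))

  r2 <- r; r2["a", "b"] <- r2["b", "a"] <- 0.99999999
  expect_warning(z2 <- fisher_z(correlation_matrix(r2)), "clipped")
  expect_true(all(is.finite(z2$values)))
  expect_error(fisher_z(z), "already")
})

test_that("partial correlation follows the closed form and its limits", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.6   # C(i,k)
  r[1, 3] <- r[3, 1] <- 0.5   # C(i,j)
  r[2, 3] <- r[3, 2] <- 0.5   # C(k,j)
  cm <- correlation_matrix(r)
  expect_equal(partial_correlation(cm, 1, 2, 3), 0.35 / 0.75)
  expect_equal(partial_correlation(cm, 1, 2, 3), oracle_pc(r, 1, 2, 3))

  # zero conditioning correlations: PC reduces to C(i,k)
  r0 <- diag(3); r0[1, 2] <- r0[2, 1] <- 0.6
  expect_equal(partial_correlation(correlation_matrix(r0), 1, 2, 3), 0.6)

  expect_error(partial_correlation(cm, 1, 1, 3), "distinct")
})

test_that("partial correlation removes a common cause (residual identity)", {
  set.seed(21)
  t <- 5000
  s <- rnorm(t)
  X <- cbind(i = s + rnorm(t), k = s + rnorm(t), j = s)
  cm <- pearson_correlations(X)
  pc <- partial_correlation(cm, "i", "k", "j")
  expect_lt(abs(pc), 0.05)
  expect_equal(pc, residual_pc(X, 1, 2, 3), tolerance = 1e-10)
})

test_that("degenerate conditioning (|r| = 1) errors with the pair named", {
  x <- rnorm(50)
  m <- cbind(a = x, b = x, c = rnorm(50))
  cm <- pearson_correlations(m)
  expect_error(partial_correlation(cm, "a", "c", "b"), "degenerate")
  expect_error(dependency_matrix(cm), "degenerate")
  expect_silent(dependency_matrix(cm, degenerate = "clip"))
})

test_that("influence d: zeroing rule, symmetry, arithmetic", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.6
  r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- 0.5
  cm <- correlation_matrix(r)
  expect_equal(influence_d(cm, 1, 2, 3), 0.6 - 0.35 / 0.75)
  expect_equal(influence_d(cm, 1, 2, 3), influence_d(cm, 2, 1, 3))

  # PC > C(i,k): negative raw influence floored at zero
  rneg <- diag(3)
  rneg[1, 2] <- rneg[2, 1] <- 0.1
  rneg[1, 3] <- rneg[3, 1] <- 0.6
  rneg[2, 3] <- rneg[3, 2] <- -0.6
  cneg <- correlation_matrix(rneg)
  expect_gt(oracle_pc(rneg, 1, 2, 3), rneg[1, 2])
  expect_equal(influence_d(cneg, 1, 2, 3), 0)

  # zero conditioning: d = 0
  r0 <- diag(3); r0[1, 2] <- r0[2, 1] <- 0.6
  expect_equal(influence_d(correlation_matrix(r0), 1, 2, 3), 0)
})

test_that("dependency matrix equals the literal loop oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    cm <- random_corr(n)
    D <- dependency_matrix(cm)
    expect_lt(max(abs(D$values - oracle_dependency(cm$values))), 1e-12)
    expect_true(all(D$values >= 0))
    expect_equal(unname(diag(D$values)), rep(0, n))
  }
  expect_error(dependency_matrix(random_corr(2)), "N >= 3")
})

test_that("dependency matrix is near zero for independent signals", {
  set.seed(32)
  m <- matrix(rnorm(20000 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  D <- dependency_matrix(pearson_correlations(m))
  expect_lt(max(D$values), 0.02)
})

test_that("a planted hub dominates the dependency matrix and the degree", {
  cm <- hub_model_corr(6, hub = 2L, alpha = 0.7)
  D <- dependency_matrix(cm)$values
  hub_col <- D[-2L, 2L]
  other_max <- max(D[, -2L])
  expect_gt(min(hub_col), other_max)

  prof <- influencing_degree(dependency_matrix(cm))
  expect_equal(names(which.max(prof$scores)), "n2")
})

test_that("influencing degree: zero and single-edge cases, oracle match", {
  Dz <- structure(list(values = matrix(0, 3, 3,
                                       dimnames = list(letters[1:3],
                                                       letters[1:3])),
                       condition_tag = ""), class = "depna_dependency")
  expect_equal(unname(influencing_degree(Dz)$scores), c(0, 0, 0))
  D1 <- Dz
  D1$values[2, 1] <- 0.3
  expect_equal(influencing_degree(D1)$scores,
               c(a = 0.3, b = 0, c = 0))

  set.seed(33)
  cm <- random_corr(7)
  expect_equal(unname(influencing_degree(dependency_matrix(cm))$scores),
               oracle_degree(oracle_dependency(cm$values)))
})

test_that("hub recovery by influencing degree across seeded replicates", {
  hits <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    x <- hub_model_data(t = 120, n = 6, hub = 3L, alpha = 0.8)
    prof <- influencing_degree(dependency_matrix(pearson_correlations(x)))
    if (which.max(prof$scores) == 3L) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("intra-network influence equals the sub-network pipeline", {
  set.seed(41)
  rs <- toy_roiset(3, 4)
  cm <- random_corr(7)
  prof <- intra_network_influence(cm, rs, "regulation")
  idx <- 4:7
  expect_equal(unname(prof$scores), oracle_intra(cm$values, idx),
               tolerance = 1e-12)
  # definitional identity: global pipeline run on the sub-matrix alone
  sub <- correlation_matrix(cm$values[idx, idx])
  expect_equal(unname(prof$scores),
               unname(influencing_degree(dependency_matrix(sub))$scores))
  expect_error(intra_network_influence(cm, rs, "nosuch"), "unknown network")
  rs2 <- roi_set(paste0("n", 1:7), c(rep("reactivity", 5), rep("regulation", 2)))
  expect_error(intra_network_influence(cm, rs2, "regulation"), ">= 3")
})

test_that("intra influence of an independent sub-network is near zero", {
  set.seed(42)
  rs <- toy_roiset(3, 4)
  m <- matrix(rnorm(20000 * 7), ncol = 7,
              dimnames = list(NULL, paste0("n", 1:7)))
  prof <- intra_network_influence(pearson_correlations(m), rs, "regulation")
  expect_lt(max(prof$scores), 0.02)
})

test_that("intra influence peaks at a hub planted inside the sub-network", {
  set.seed(43)
  rs <- toy_roiset(3, 4)
  x <- matrix(rnorm(3000 * 7), 3000, 7, dimnames = list(NULL, paste0("n", 1:7)))
  h <- rnorm(3000)
  x[, 5] <- h                          # hub inside regulation
  for (i in c(4, 6, 7)) x[, i] <- 0.7 * h + rnorm(3000)
  prof <- intra_network_influence(pearson_correlations(x), rs, "regulation")
  expect_equal(names(which.max(prof$scores)), "n5")
})

test_that("inter-network influences equal their pair-loop oracles", {
  set.seed(51)
  rs <- toy_roiset(3, 4)
  for (rep in 1:10) {
    cm <- random_corr(7)
    src <- 4:7; tgt <- 1:3
    for (norm in c("mean", "sum")) {
      w <- inter_network_influence_within(cm, rs, "regulation", "reactivity",
                                          normalization = norm)
      expect_equal(unname(w$scores),
                   oracle_inter_within(cm$values, src, tgt, norm),
                   tolerance = 1e-12)
      b <- inter_network_influence_between(cm, rs, "regulation", "reactivity",
                                           normalization = norm)
      expect_equal(unname(b$scores),
                   oracle_inter_between(cm$values, src, tgt, norm),
                   tolerance = 1e-12)
    }
  }
})

test_that("inter-network influence of a cross-network common cause", {
  # j (regulation) drives every reactivity node: with the noise-free hub
  # correlation structure, PC(i,k|j) = 0 for target pairs, so the mean
  # influence approaches the mean target-pair correlation.
  rs <- toy_roiset(3, 4)
  cm <- hub_model_corr(7, hub = 4L, alpha = 0.6)
  w <- inter_network_influence_within(cm, rs, "regulation", "reactivity")
  tgt_pairs <- cm$values[1:3, 1:3][upper.tri(diag(3))]
  expect_equal(unname(w$scores["n4"]), mean(tgt_pairs), tolerance = 1e-10)

  # independent j: near-zero influence
  set.seed(52)
  m <- matrix(rnorm(20000 * 7), ncol = 7,
              dimnames = list(NULL, paste0("n", 1:7)))
  w0 <- inter_network_influence_within(pearson_correlations(m), rs,
                                       "regulation", "reactivity")
  expect_lt(max(w0$scores), 0.02)
})

test_that("total inter-network influence sums per-node scores", {
  prof <- influence_profile("inter_within_other",
                            c(a = 0.1, b = 0.2),
                            source_network = "regulation",
                            target_network = "reactivity")
  expect_equal(total_inter_network_influence(prof), 0.3)
  zero <- influence_profile("inter_between", c(a = 0, b = 0))
  expect_equal(total_inter_network_influence(zero), 0)
  glob <- influence_profile("global_degree", c(a = 1))
  expect_error(total_inter_network_influence(glob), "scheme")

  set.seed(53)
  rs <- toy_roiset(3, 4)
  cm <- random_corr(7)
  w <- inter_network_influence_within(cm, rs, "regulation", "reactivity")
  expect_equal(total_inter_network_influence(w),
               sum(oracle_inter_within(cm$values, 4:7, 1:3)))
})

test_that("every influence quantity is non-negative and d is symmetric", {
  set.seed(61)
  rs <- toy_roiset(3, 4)
  for (rep in 1:10) {
    cm <- random_corr(7)
    D <- dependency_matrix(cm)
    expect_true(all(D$values >= 0))
    expect_true(all(influencing_degree(D)$scores >= 0))
    for (pick in 1:5) {
      ikj <- sample(7, 3)
      expect_identical(influence_d(cm, ikj[1], ikj[2], ikj[3]),
                       influence_d(cm, ikj[2], ikj[1], ikj[3]))
    }
    expect_true(all(inter_network_influence_within(
      cm, rs, "regulation", "reactivity")$scores >= 0))
    expect_true(all(inter_network_influence_between(
      cm, rs, "regulation", "reactivity")$scores >= 0))
  }
})

test_that("relabeling / reordering ROIs permutes all outputs consistently", {
  set.seed(62)
  rs <- toy_roiset(3, 4)
  cm <- random_corr(7)
  perm <- sample(7)
  labels_p <- paste0("n", 1:7)[perm]
  cm_p <- correlation_matrix(cm$values[perm, perm])
  rs_p <- roi_set(labels_p, rs$network[labels_p])

  D <- dependency_matrix(cm)$values
  D_p <- dependency_matrix(cm_p)$values
  expect_equal(D_p, D[perm, perm])

  deg <- influencing_degree(dependency_matrix(cm))$scores
  deg_p <- influencing_degree(dependency_matrix(cm_p))$scores
  expect_equal(deg_p, deg[labels_p])

  intra <- intra_network_influence(cm, rs, "regulation")$scores
  intra_p <- intra_network_influence(cm_p, rs_p, "regulation")$scores
  expect_equal(sort(names(intra)), sort(names(intra_p)))
  expect_equal(intra_p[names(intra)[order(names(intra))]],
               intra[order(names(intra))])
})

test_that("hub influencing degree grows with coupling (noise-free oracle)", {
  degs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(alpha) {
    cm <- hub_model_corr(6, hub = 1L, alpha = alpha)
    influencing_degree(dependency_matrix(cm))$scores[["n1"]]
  }, numeric(1))
  expect_true(all(diff(degs) >= 0))
})

test_that("fisher_z analysis path runs with clipped denominators", {
  set.seed(63)
  cm <- random_corr(6)
  z <- fisher_z(cm)
  expect_warning(Dz <- dependency_matrix(z), "Fisher-z")
  expect_true(all(is.finite(Dz$values)))
  expect_true(all(Dz$values >= 0))
})
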