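test_that("paired condition t-test: identity, shift and degenerate cases", {
  set.seed(81)
  lo <- matrix(rnorm(20 * 3), 20, dimnames = list(sprintf("s%02d", 1:20),
                                                  c("a", "b", "c")))
  same <- paired_condition_ttest(lo, lo)
  expect_equal(same$t, rep(0, 3))
  expect_equal(same$p, rep(1, 3))
  expect_true(all(same$degenerate))

  hi <- lo + 1                      # zero-variance positive differences
  shift <- paired_condition_ttest(lo, hi)
  expect_true(all(shift$t == Inf))
  expect_equal(shift$p, rep(0, 3))
  expect_true(all(shift$degenerate))
  expect_equal(shift$direction, rep(1, 3))

  # ordinary case agrees with stats::t.test
  hi2 <- lo + matrix(rnorm(60, 0.3, 1), 20)
  colnames(hi2) <- colnames(lo); rownames(hi2) <- rownames(lo)
  out <- paired_condition_ttest(lo, hi2)
  ref <- t.test(hi2[, 2], lo[, 2], paired = TRUE)
  expect_equal(out$t[2], unname(ref$statistic))
  expect_equal(out$p[2], ref$p.value)
  expect_equal(out$df[2], unname(ref$parameter))

  # subject alignment: shuffled rows are re-matched by id
  shuffled <- hi2[sample(rownames(hi2)), ]
  expect_equal(paired_condition_ttest(lo, shuffled)$t, out$t)
  rownames(shuffled) <- paste0("x", 1:20)
  expect_error(paired_condition_ttest(lo, shuffled), "subject")
})

test_that("planted hub-shift cohort: hub node attains the largest |t|", {
  spec <- cohort_spec(seed = 1)
  cohort <- simulate_cohort(spec)
  lo <- cohort_influence(cohort$ts_low, cohort$roiset, "global_degree")
  hi <- cohort_influence(cohort$ts_high, cohort$roiset, "global_degree")
  tab <- paired_condition_ttest(lo, hi)
  expect_equal(tab$node[which.max(abs(tab$t))], "vmPFC")
  expect_equal(tab$direction[tab$node == "vmPFC"], 1)
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # family larger than the reported subset
  expect_equal(bh_fdr(c(0.01, 0.04), m = 4), c(0.04, 0.08))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "family")
})

test_that("edgewise contrast graph: null, boundary and planted-column cases", {
  set.seed(82)
  n <- 5; S <- 20
  labels <- letters[1:n]
  stack <- array(abs(rnorm(n * n * S)), c(n, n, S),
                 dimnames = list(labels, labels, NULL))
  for (s in 1:S) diag(stack[, , s]) <- 0

  g0 <- edge_contrast_graph(stack, stack)
  expect_equal(nrow(g0$edges), 0)
  expect_equal(g0$nodes$score, rep(0, n))

  g_all <- edge_contrast_graph(stack, stack + 0.1, alpha = 1)
  expect_equal(nrow(g_all$edges), n * (n - 1))

  # planted increase only in column 2: edges originate at node 2, with
  # off-column type-I strays at rate <= alpha over seeds
  stray_rates <- vapply(1:50, function(seed) {
    set.seed(seed)
    lo <- array(abs(rnorm(n * n * S)), c(n, n, S),
                dimnames = list(labels, labels, NULL))
    hi <- lo + array(rnorm(n * n * S, 0, 0.2), c(n, n, S))
    hi[, 2, ] <- hi[, 2, ] + 0.6
    g <- edge_contrast_graph(lo, hi, alpha = 0.05)
    from2 <- g$edges$from == "b"
    expect_equal(sum(from2), n - 1)       # every column-2 edge recovered
    sum(!from2) / (n * (n - 1) - (n - 1)) # stray rate among other entries
  }, numeric(1))
  expect_lt(mean(stray_rates), 0.05 + 2 * sqrt(0.05 * 0.95 / (50 * 16)))

  dimnames(stack)[[1]] <- LETTERS[1:n]
  expect_error(edge_contrast_graph(stack, g0$t_matrix), "aligned")
})

test_that("behavior correlation applies listwise deletion and the SD rule", {
  set.seed(83)
  delta <- rnorm(30)
  expect_equal(behavior_correlation(delta, 2 * delta)$r, 1)

  beh <- delta + rnorm(30, 0, 0.5)
  base <- behavior_correlation(delta, beh)
  ref <- cor.test(delta, beh)
  expect_equal(base$r, unname(ref$estimate))
  expect_equal(base$p, ref$p.value)
  expect_equal(base$n_used, 30)

  # one 5-SD outlier on the behavior side is excluded
  beh_out <- beh
  beh_out[7] <- mean(beh) + 5 * sd(beh)
  out <- behavior_correlation(delta, beh_out)
  expect_equal(out$n_used, 29)
  expect_equal(out$excluded, 7L)

  # missing behavior removed listwise
  beh_na <- beh; beh_na[c(2, 9)] <- NA
  expect_equal(behavior_correlation(delta, beh_na)$n_used, 28)

  expect_error(behavior_correlation(delta[1:3], beh[1:3]), "4 complete")
})

test_that("behavior coupling is recovered from generator cohorts", {
  hits <- 0L
  n_rep <- 25L
  for (seed in seq_len(n_rep)) {
    cohort <- simulate_cohort(cohort_spec(n_subjects = 70, seed = seed + 200))
    lo <- cohort_influence(cohort$ts_low, cohort$roiset, "global_degree")
    hi <- cohort_influence(cohort$ts_high, cohort$roiset, "global_degree")
    delta <- lo[, "vmPFC"] - hi[, "vmPFC"]
    res <- behavior_correlation(delta, cohort$behavior$anger_auc)
    if (res$r < 0 && res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("specificity bootstrap counts extremeness in the observed direction", {
  rand <- seq(-2, 2, length.out = 1000)
  top <- specificity_bootstrap(3, rand)
  expect_equal(top$p, 1 / 1001)
  # positive observed inside the distribution
  expect_equal(suppressWarnings(specificity_bootstrap(2, c(-3, -1, 0, 1, 3),
                                                      mode = "tstat"))$p,
               (1 + 1) / 6)
  # negative observed: extremeness flips direction
  neg <- specificity_bootstrap(-3, rand)
  expect_equal(neg$p, 1 / 1001)
  expect_equal(neg$direction, -1)
  # literal formula: smaller-than-observed count regardless of sign
  lit <- specificity_bootstrap(-3, rand, literal_eq5 = TRUE)
  expect_equal(lit$p, 1 / 1001)
  lit_hi <- specificity_bootstrap(3, rand, literal_eq5 = TRUE)
  expect_equal(lit_hi$p, 1)

  expect_error(specificity_bootstrap(1, numeric(0)), "k >= 1")
  expect_warning(specificity_bootstrap(1, rnorm(50)), "coarse")
})

test_that("bootstrap p is uniform when observed and randoms share a null", {
  set.seed(84)
  k <- 999
  # one-signed statistics: the direction-oriented count reduces to a plain
  # rank, which is exactly uniform for exchangeable draws
  pvals_pos <- vapply(1:500, function(r) {
    stats <- abs(rnorm(k + 1))
    specificity_bootstrap(stats[1], stats[-1])$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals_pos, "punif"))$p.value, 0.01)
  # the literal printed formula (count random <= observed) is rank-uniform
  # for signed statistics too
  pvals_lit <- vapply(1:500, function(r) {
    stats <- rnorm(k + 1)
    specificity_bootstrap(stats[1], stats[-1], literal_eq5 = TRUE)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals_lit, "punif"))$p.value, 0.01)
})

test_that("random network stats draw size-matched subsets from the pool", {
  pool <- simulate_null_pool(t = 60, n_pool = 30, seed = 5)
  expect_equal(dim(pool), c(60, 30))
  expect_identical(pool, simulate_null_pool(t = 60, n_pool = 30, seed = 5))
  set.seed(85)
  stats <- random_network_stats(30, 5, 40, function(idx) {
    expect_length(idx, 5)
    max(abs(pearson_correlations(pool[, idx])$values -
              diag(5)))
  })
  expect_length(stats, 40)
  expect_true(all(stats > 0 & stats < 1))
  expect_error(random_network_stats(4, 5, 10, identity), "smaller")
})
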