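test_that("pointwise t statistics match the one-sample formula", {
  acc <- c(0.55, 0.60, 0.50, 0.65, 0.55)
  mat <- matrix(acc, ncol = 1)
  # direct arithmetic oracle
  t_hand <- (mean(acc) - 0.5) / (sd(acc) / sqrt(5))
  expect_equal(pointwise_tstats(mat), t_hand, ignore_attr = TRUE)
  # all participants exactly at chance
  expect_equal(pointwise_tstats(matrix(0.5, 4, 6)), rep(0, 6))
  # degenerate variance -> infinite sentinels
  expect_equal(pointwise_tstats(matrix(0.6, 4, 1)), Inf)
  expect_equal(pointwise_tstats(matrix(0.4, 4, 1)), -Inf)
  expect_error(pointwise_tstats(matrix(0.5, 1, 3)), ">= 2")
})

test_that("clusters are maximal runs above the critical value", {
  t <- c(0, 0, 3, 3, 3, 0)
  cl <- form_clusters(t, n = 16, alpha_forming = 0.05)
  # qt(0.95, 15) = 1.753: single run over positions 3..5
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 3)
  expect_equal(cl$end, 5)
  expect_equal(cl$mass, 9)
  # all sub-threshold -> empty
  expect_equal(nrow(form_clusters(rep(0.5, 10), n = 16)), 0)
  # two runs separated by one sub-threshold point stay separate
  cl2 <- form_clusters(c(3, 3, 0, 3, 3), n = 16)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$start, c(1, 4))
  # infinite sentinels contribute a capped mass
  cl3 <- form_clusters(c(0, Inf, Inf, 0), n = 16)
  expect_equal(cl3$mass, 200)
})

test_that("permutation null is reproducible and degenerate on flat data", {
  mat <- matrix(0.5, 6, 20)
  null <- permutation_null(mat, n_permutations = 50, seed = 4)
  expect_equal(null, rep(0, 50))
  set.seed(99)
  mat2 <- matrix(0.5 + rnorm(6 * 20, sd = 0.05), 6, 20)
  n1 <- permutation_null(mat2, n_permutations = 200, seed = 7)
  n2 <- permutation_null(mat2, n_permutations = 200, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, permutation_null(mat2, 200, seed = 8)))
})

test_that("cluster p-values follow the add-one estimator", {
  clusters <- tibble::tibble(start = 1L, end = 3L, mass = 50)
  null <- rep(1, 999) # every null mass below the observed
  res <- significant_clusters(clusters, null, cluster_alpha = 0.05)
  expect_equal(res$p_value, 1 / 1000)
  expect_true(res$significant)
  # zero-mass observed cluster can never be significant
  res0 <- significant_clusters(tibble::tibble(start = 1L, end = 1L, mass = 0),
                               c(0, 0, 0), 0.05)
  expect_equal(res0$p_value, 1)
  expect_false(res0$significant)
  # empty observed list passes through
  resE <- significant_clusters(form_clusters(rep(0, 5), 8), null)
  expect_equal(nrow(resE), 0)
})

test_that("Monte-Carlo cluster p matches exhaustive enumeration at n = 8", {
  set.seed(123)
  mat <- matrix(0.5 + rnorm(8 * 20, sd = 0.04), 8, 20)
  mat[, 8:12] <- mat[, 8:12] + 0.05 # a genuine bump
  t <- pointwise_tstats(mat)
  cl <- form_clusters(t, 8)
  expect_gt(nrow(cl), 0)
  null_ex <- permutation_null(mat, exhaustive = TRUE)
  expect_length(null_ex, 256)
  null_mc <- permutation_null(mat, n_permutations = 5000, seed = 31)
  for (m in cl$mass) {
    p_ex <- (1 + sum(null_ex >= m)) / (1 + length(null_ex))
    p_mc <- (1 + sum(null_mc >= m)) / (1 + length(null_mc))
    expect_lt(abs(p_ex - p_mc), 0.02)
  }
})

test_that("cluster masses ignore constant shifts at sub-threshold timepoints", {
  set.seed(5)
  mat <- matrix(0.5 + rnorm(10 * 30, sd = 0.01), 10, 30)
  mat[, 10:14] <- mat[, 10:14] + 0.2
  t0 <- pointwise_tstats(mat)
  cl0 <- form_clusters(t0, 10)
  # shift all participants equally at timepoints outside the cluster,
  # keeping them sub-threshold
  mat2 <- mat
  mat2[, 25:30] <- mat2[, 25:30] - 0.004
  cl1 <- form_clusters(pointwise_tstats(mat2), 10)
  in_cl <- cl0[cl0$start <= 14 & cl0$end >= 10, ]
  in_cl2 <- cl1[cl1$start <= 14 & cl1$end >= 10, ]
  expect_equal(in_cl2$mass, in_cl$mass)
})

test_that("full cluster test flags an injected effect and not flat data", {
  set.seed(77)
  mat <- matrix(0.5 + rnorm(8 * 40, sd = 0.03), 8, 40)
  mat[, 15:22] <- mat[, 15:22] + 0.12
  attr(mat, "times") <- seq(0, by = 8, length.out = 40)
  res <- cluster_test(mat, n_permutations = 500, seed = 3)
  sig <- res[res$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$start <= 15 & sig$end >= 22))
  expect_true(all(c("start_ms", "end_ms") %in% names(sig)))
  g <- glance(res)
  expect_equal(g$n_permutations, 500)
  expect_gte(g$n_significant, 1)
})

test_that("Bonferroni pointwise correction uses alpha / n_timepoints", {
  set.seed(12)
  mat <- matrix(0.5 + rnorm(10 * 125, sd = 0.02), 10, 125)
  mat[, 60] <- 0.9 # one extreme timepoint
  mat[, 61] <- 0.6
  res <- bonferroni_pointwise(mat, alpha = 0.05)
  expect_equal(nrow(res), 125)
  # per-test threshold 0.05 / 125 = 4e-4
  expect_identical(res$significant, res$p_value < 4e-4)
  expect_true(res$significant[60])
  # chance-only columns stay unflagged
  expect_equal(sum(res$significant[-(60:61)]), 0)
  # infinite t is always flagged
  mat2 <- matrix(0.7, 4, 3)
  mat2[, 2] <- c(0.4, 0.5, 0.6, 0.5)
  res2 <- bonferroni_pointwise(mat2)
  expect_true(all(res2$significant[c(1, 3)]))
})
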