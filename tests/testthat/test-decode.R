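test_that("1-D symmetric problem puts the boundary at zero", {
  X <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c("A", "A", "B", "B")
  m <- fit_linear_svm(X, y, cost = 1)
  # decision value at the midpoint is 0 -> tie goes to the lower sort order
  p <- predict(m, matrix(c(0.5, -0.5, 0), ncol = 1))
  expect_equal(p[1], "B", ignore_attr = TRUE)
  expect_equal(p[2], "A", ignore_attr = TRUE)
  expect_equal(attr(p, "decision")[3], 0, tolerance = 1e-9)
  expect_equal(p[3], "A", ignore_attr = TRUE) # exact tie -> lower sort order
  expect_error(fit_linear_svm(X, rep("A", 4)), "two classes")
})

test_that("solver margin matches a brute-force direction search", {
  # hard-margin limit on small separable 2-D sets; oracle scans unit-norm
  # directions and, for each, the best symmetric boundary
  brute_margin <- function(X, y) {
    best <- 0
    for (th in seq(0, pi, length.out = 20000)) {
      w <- c(cos(th), sin(th))
      pa <- X[y == "A", ] %*% w
      pb <- X[y == "B", ] %*% w
      gap <- min(pb) - max(pa)
      best <- max(best, gap / 2)
    }
    best
  }
  sets <- list(
    list(X = rbind(c(0, 0), c(1, 0), c(0, 3), c(1, 3)),
         y = c("A", "A", "B", "B")),
    list(X = rbind(c(-1, -1), c(-2, 1), c(1.5, 0.5), c(2, -1)),
         y = c("A", "A", "B", "B")),
    list(X = rbind(c(0, 0), c(2, 0.5), c(1, 2), c(3, 2.5)),
         y = c("A", "A", "B", "B"))
  )
  for (s in sets) {
    m <- fit_linear_svm(s$X, s$y, cost = 1e5)
    expect_equal(1 / sqrt(sum(m$w^2)), brute_margin(s$X, s$y),
                 tolerance = 1e-3)
  }
})

test_that("identical points with opposite labels give chance behaviour", {
  X <- matrix(rnorm(20), 10, 2)
  m <- fit_linear_svm(rbind(X, X), rep(c("A", "B"), each = 10), cost = 1)
  p <- predict(m, X)
  expect_true(all(abs(attr(p, "decision")) < 1e-6))
})

test_that("the two solver engines agree", {
  for (trial in 1:40) {
    set.seed(trial + 300)
    X <- matrix(rnorm(42 * 16), 42, 16)
    y <- rep(c("A", "B"), each = 21)
    m1 <- fit_linear_svm(X, y, cost = 1, engine = "smo")
    m2 <- fit_linear_svm(X, y, cost = 1, engine = "libsvm")
    Xt <- matrix(rnorm(30 * 16), 30, 16)
    d1 <- attr(predict(m1, Xt), "decision")
    d2 <- attr(predict(m2, Xt), "decision")
    expect_equal(d1, d2, tolerance = 0.05)
  }
})

test_that("LOO fold scheme holds out one pseudo-epoch per class", {
  folds <- middecode:::loo_folds(21, "paired")
  expect_length(folds, 21)
  for (k in seq_along(folds)) {
    expect_equal(folds[[k]]$test, c(k, 21 + k))
    expect_length(setdiff(1:42, folds[[k]]$test), 40) # 40 training epochs
  }
  expect_length(middecode:::loo_folds(21, "single"), 42)
})

test_that("separable pseudo-epochs decode perfectly; t_index validated", {
  e <- make_label_epochs(40, conds = c("A", "B"), n_ch = 4, n_t = 6,
                         noise_sd = 0.1,
                         cond_means = list(A = matrix(5, 4, 6),
                                           B = matrix(-5, 4, 6)))
  pe <- draw_mean_epochs(build_pool(e), n_draw = 4, n_means = 10, seed = 1)
  expect_equal(loo_accuracy_at_timepoint(pe, c("A", "B"), 3), 1.0)
  expect_error(loo_accuracy_at_timepoint(pe, c("A", "B"), 7), "out of range")
})

test_that("LOO accuracy equals an explicit fold-by-fold enumeration", {
  set.seed(17)
  e <- make_label_epochs(40, conds = c("A", "B"), n_ch = 6, n_t = 4,
                         noise_sd = 1,
                         cond_means = list(A = matrix(0.8, 6, 4)))
  pe <- draw_mean_epochs(build_pool(e), n_draw = 4, n_means = 8, seed = 5)
  t_idx <- 2
  # independent oracle: iterate folds explicitly with the libsvm engine
  X <- rbind(pe$classes$A[, , t_idx], pe$classes$B[, , t_idx])
  y <- rep(c("A", "B"), each = 8)
  correct <- 0
  for (k in 1:8) {
    test <- c(k, 8 + k)
    fit <- e1071::svm(X[-test, ], factor(y[-test]), kernel = "linear",
                      cost = 1, scale = FALSE)
    correct <- correct + sum(as.character(predict(fit, X[test, ])) == y[test])
  }
  expect_equal(loo_accuracy_at_timepoint(pe, c("A", "B"), t_idx),
               correct / 16)
})

test_that("label-independent features decode at chance on average", {
  accs <- vapply(1:25, function(s) {
    e <- make_label_epochs(40, conds = c("A", "B"), n_ch = 6, n_t = 2,
                           noise_sd = 1, seed = 1000 + s)
    pe <- draw_mean_epochs(build_pool(e), n_draw = 4, n_means = 10,
                           seed = s)
    loo_accuracy_at_timepoint(pe, c("A", "B"), 1)
  }, 0)
  n_cls <- 25 * 20
  half_width <- 1.96 * sqrt(0.25 / n_cls)
  expect_lt(abs(mean(accs) - 0.5), half_width + 0.02)
})

test_that("decoding timecourses carry shape and stay within a signal window", {
  e <- make_label_epochs(60, conds = c("A", "B"), n_ch = 6, n_t = 12,
                         noise_sd = 1, seed = 2,
                         cond_means = list(A = cbind(matrix(0, 6, 6),
                                                     matrix(2, 6, 6))))
  pool <- build_pool(e)
  cfg <- decode_config(n_iterations = 4, n_draw = 5, n_means = 12,
                       base_seed = 3)
  tc <- decode_timecourse(pool, c("A", "B"), cfg)
  expect_s3_class(tc, "decoding_timecourse")
  expect_equal(nrow(tc), 12)
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  # information exists only in the second half
  expect_lt(mean(tc$accuracy[1:6]), 0.65)
  expect_gt(mean(tc$accuracy[7:12]), 0.9)
  g <- glance(tc)
  expect_equal(g$comparison, "A vs B")
  expect_gte(g$peak_latency_ms, tc$time_ms[7])
})

test_that("accuracy is invariant to channel permutation and global scaling", {
  base <- make_label_epochs(50, conds = c("A", "B"), n_ch = 5, n_t = 4,
                            noise_sd = 1, seed = 6,
                            cond_means = list(A = matrix(0.7, 5, 4)))
  cfg <- decode_config(n_iterations = 3, n_draw = 5, n_means = 10,
                       base_seed = 11)
  tc0 <- decode_timecourse(build_pool(base), c("A", "B"), cfg)
  perm <- c(4, 2, 5, 1, 3)
  permuted <- epoch_set(base$data[, perm, , drop = FALSE], base$labels,
                        base$times, base$rate_hz)
  tc_p <- decode_timecourse(build_pool(permuted), c("A", "B"), cfg)
  expect_equal(tc_p$accuracy, tc0$accuracy)
  scaled <- epoch_set(base$data * 37, base$labels, base$times, base$rate_hz)
  tc_s <- decode_timecourse(build_pool(scaled), c("A", "B"), cfg)
  expect_equal(tc_s$accuracy, tc0$accuracy)
})

test_that("cross-decoding transfers only shared information", {
  # class difference along channel 1 is shared between domains; channel 2
  # carries domain-specific information only
  mk <- function(ch, val, n_ch = 4, n_t = 3) {
    m <- matrix(0, n_ch, n_t); m[ch, ] <- val; m
  }
  e <- make_label_epochs(
    60, conds = c("CD_TOWARD", "CD_AWAY", "IOVD_TOWARD", "IOVD_AWAY"),
    n_ch = 4, n_t = 3, noise_sd = 1, seed = 8,
    cond_means = list(CD_TOWARD = mk(1, 1.5) + mk(2, 2),
                      CD_AWAY = mk(1, -1.5) + mk(2, -2),
                      IOVD_TOWARD = mk(1, 1.5) + mk(3, 2),
                      IOVD_AWAY = mk(1, -1.5) + mk(3, -2)))
  pool <- build_pool(e)
  cfg <- decode_config(n_iterations = 4, n_draw = 5, n_means = 12,
                       base_seed = 5)
  tcx <- cross_decode_timecourse(pool, c("CD_TOWARD", "CD_AWAY"),
                                 c("IOVD_TOWARD", "IOVD_AWAY"), cfg)
  expect_gt(mean(tcx$accuracy), 0.8) # the shared channel transfers
  expect_error(
    cross_decode_timecourse(pool, c("CD_TOWARD", "CD_AWAY"),
                            c("CD_TOWARD", "IOVD_TOWARD"), cfg),
    "semantics")
  # train = test pair: resubstitution accuracy bounds the LOO accuracy
  tc_same <- cross_decode_timecourse(pool, c("CD_TOWARD", "CD_AWAY"),
                                     c("CD_TOWARD", "CD_AWAY"), cfg)
  tc_loo <- decode_timecourse(pool, c("CD_TOWARD", "CD_AWAY"), cfg)
  expect_true(all(tc_same$accuracy - tc_loo$accuracy >= -0.05))
})

test_that("relabeling reproduces condition decoding and rebalances", {
  e <- make_label_epochs(60, conds = c("A", "B"), n_ch = 4, n_t = 3,
                         noise_sd = 1, seed = 9,
                         cond_means = list(A = matrix(1, 4, 3)))
  cfg <- decode_config(n_iterations = 3, n_draw = 5, n_means = 10,
                       base_seed = 21)
  tc_direct <- decode_timecourse(build_pool(e), c("A", "B"), cfg)
  tc_relab <- relabel_and_decode(e, e$labels, cfg)
  expect_equal(tc_relab$accuracy, tc_direct$accuracy)
  # unbalanced labels trigger a warning and stratified subsampling
  lab <- c(rep("X", 70), rep("Y", 50))
  expect_warning(tc_unbal <- relabel_and_decode(e, lab, cfg), "unbalanced")
  expect_s3_class(tc_unbal, "decoding_timecourse")
  expect_error(relabel_and_decode(e, rep("X", 120), cfg), "two classes")
})
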