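#' Decoding configuration
#'
#' @param n_iterations Bootstrap iterations averaged per timepoint.
#' @param n_draw Raw epochs averaged into one pseudo-epoch.
#' @param n_means Pseudo-epochs per class and iteration.
#' @param cost Soft-margin cost C of the linear SVM.
#' @param fold_scheme `"paired"` holds out one pseudo-epoch per class per
#'   fold (21 folds, 40 training epochs, 2 test items at defaults);
#'   `"single"` is plain leave-one-out over all 42 pseudo-epochs (41 train).
#' @param base_seed Seed of the bootstrap stream.
#' @param keep_iterations Retain the per-iteration accuracy matrix (for
#'   variance estimates / error ribbons).
#' @return A `decode_config` list.
#' @export
decode_config <- function(n_iterations = 1000, n_draw = 10, n_means = 21,
                          cost = 1, fold_scheme = c("paired", "single"),
                          base_seed = 1L, keep_iterations = FALSE) {
  fold_scheme <- match.arg(fold_scheme)
  structure(
    list(n_iterations = n_iterations, n_draw = n_draw, n_means = n_means,
         cost = cost, fold_scheme = fold_scheme,
         base_seed = as.integer(base_seed),
         keep_iterations = keep_iterations),
    class = "decode_config"
  )
}

#' Fit a soft-margin linear SVM
#'
#' Solves the linear C-SVC dual and returns the primal weight vector and
#' bias, oriented so that a positive decision value predicts the class that
#' sorts first. The default engine is a compiled in-package SMO solver
#' (maximal-violating-pair working set, libsvm stopping rule);
#' `engine = "libsvm"` routes the identical problem through e1071/libsvm
#' instead, which is useful for cross-validation of the solver itself.
#' Deterministic given `(X, y, cost)`.
#'
#' @param X Numeric feature matrix, one row per observation.
#' @param y Two-class label vector.
#' @param cost Soft-margin cost C.
#' @param engine `"smo"` (compiled, default) or `"libsvm"` (e1071).
#' @return A `linear_model` with elements `w`, `b`, `levels`, `cost`.
#' @export
fit_linear_svm <- function(X, y, cost = 1, engine = c("smo", "libsvm")) {
  engine <- match.arg(engine)
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2L) abort("`y` must contain exactly two classes")
  if (nrow(X) < 2L) abort("need at least two observations")
  if (engine == "smo") {
    ypm <- ifelse(y == lv[1], 1, -1)
    fit <- .svm_linear_smo(X, ypm, cost)
    w <- fit$w
    b <- fit$b
  } else {
    fit <- e1071::svm(X, factor(y, levels = lv), kernel = "linear",
                      cost = cost, scale = FALSE, fitted = FALSE)
    w <- as.vector(crossprod(fit$SV, fit$coefs))
    b <- -fit$rho
    # libsvm orients the decision value toward the first label it encounters
    if (fit$levels[fit$labels[1]] != lv[1]) {
      w <- -w
      b <- -b
    }
  }
  structure(list(w = as.vector(w), b = b, levels = lv, cost = cost),
            class = "linear_model")
}

#' @describeIn fit_linear_svm Predict labels; decision values are attached
#'   as attribute `"decision"`. Exact ties (decision value 0) go to the
#'   class with the lower sort order.
#' @param object A `linear_model`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  dv <- as.vector(newdata %*% object$w + object$b)
  out <- ifelse(dv >= 0, object$levels[1], object$levels[2])
  attr(out, "decision") <- dv
  out
}

# fold index sets for the paired leave-one-out scheme
loo_folds <- function(n_means, scheme = "paired") {
  if (scheme == "paired") {
    lapply(seq_len(n_means), function(k) list(test = c(k, n_means + k)))
  } else {
    lapply(seq_len(2L * n_means), function(k) list(test = k))
  }
}

# internal: LOO accuracy given the two class feature matrices at a timepoint
loo_accuracy_matrices <- function(X1, X2, cost, scheme) {
  n <- nrow(X1)
  X <- rbind(X1, X2)
  y <- rep(c("A", "B"), each = n)
  folds <- loo_folds(n, scheme)
  correct <- 0L
  for (f in folds) {
    train <- setdiff(seq_len(2L * n), f$test)
    mod <- fit_linear_svm(X[train, , drop = FALSE], y[train], cost)
    pred <- predict(mod, X[f$test, , drop = FALSE])
    correct <- correct + sum(pred == y[f$test])
  }
  correct / (2L * n)
}

#' Leave-one-out decoding accuracy at one timepoint
#'
#' Features are the channel values of each pseudo-epoch at the requested
#' timepoint. Under the default `"paired"` scheme the classifier is trained
#' on 40 pseudo-epochs and tested on the held-out pseudo-epoch of each class
#' (21 folds, 42 classifications at defaults).
#'
#' @param pseudo A `pseudo_epoch_set`.
#' @param pair Length-2 character vector of class names.
#' @param t_index Timepoint index.
#' @param cost SVM cost.
#' @param fold_scheme See [decode_config()].
#' @return Accuracy fraction in `[0, 1]`.
#' @export
loo_accuracy_at_timepoint <- function(pseudo, pair, t_index, cost = 1,
                                      fold_scheme = "paired") {
  stopifnot(inherits(pseudo, "pseudo_epoch_set"))
  if (t_index < 1L || t_index > length(pseudo$times)) {
    abort("`t_index` out of range")
  }
  X1 <- pseudo$classes[[pair[1]]][, , t_index, drop = TRUE]
  X2 <- pseudo$classes[[pair[2]]][, , t_index, drop = TRUE]
  loo_accuracy_matrices(X1, X2, cost, fold_scheme)
}

new_decoding_timecourse <- function(times, acc, comparison, participant,
                                    cfg, iterations = NULL) {
  out <- tibble::tibble(time_ms = times, accuracy = acc)
  class(out) <- c("decoding_timecourse", class(out))
  attr(out, "comparison") <- comparison
  attr(out, "participant") <- participant
  attr(out, "n_iterations") <- cfg$n_iterations
  attr(out, "fold_scheme") <- cfg$fold_scheme
  attr(out, "seed") <- cfg$base_seed
  attr(out, "iterations") <- iterations
  out
}

#' Per-timepoint bootstrap-SVM decoding timecourse
#'
#' For every bootstrap iteration, draws a fresh set of pseudo-epochs for the
#' two classes and computes the leave-one-out accuracy at every timepoint;
#' returns the per-timepoint mean over iterations.
#'
#' @param pool A `sampling_pool` (possibly pooled via [pool_conditions()]).
#' @param pair Length-2 character vector naming the classes to decode.
#' @param cfg A [decode_config()].
#' @return A `decoding_timecourse` tibble (`time_ms`, `accuracy`) carrying
#'   the comparison name, participant, iteration count, fold scheme and seed
#'   as attributes.
#' @export
decode_timecourse <- function(pool, pair, cfg = decode_config()) {
  pool <- pool_subset(pool, pair)
  it <- bootstrap_iterator(pool, cfg$n_iterations, cfg$base_seed,
                           cfg$n_draw, cfg$n_means)
  n_t <- length(pool$times)
  acc <- matrix(0, n_t, cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    pe <- it$draw(i)
    A1 <- pe$classes[[pair[1]]]
    A2 <- pe$classes[[pair[2]]]
    for (t in seq_len(n_t)) {
      acc[t, i] <- loo_accuracy_matrices(A1[, , t], A2[, , t],
                                         cfg$cost, cfg$fold_scheme)
    }
  }
  new_decoding_timecourse(
    pool$times, rowMeans(acc), paste(pair, collapse = " vs "),
    pool$participant_id, cfg,
    iterations = if (cfg$keep_iterations) acc else NULL)
}

condition_semantics <- function(x) sub("^[^_]*_", "", x)

#' Cross-trained decoding timecourse
#'
#' Trains the classifier on all pseudo-epochs of one condition pair (e.g. CD
#' toward vs CD away) and tests it on all pseudo-epochs of a different pair
#' sharing the same label semantics (e.g. IOVD toward vs IOVD away), per
#' iteration and timepoint. Above-chance transfer indicates information
#' shared between the two training domains.
#'
#' @param pool A four-condition `sampling_pool`.
#' @param train_pair,test_pair Length-2 condition vectors whose label
#'   suffixes (after the first underscore) must match.
#' @param cfg A [decode_config()].
#' @return A `decoding_timecourse`.
#' @export
cross_decode_timecourse <- function(pool, train_pair, test_pair,
                                    cfg = decode_config()) {
  sem_tr <- condition_semantics(train_pair)
  sem_te <- condition_semantics(test_pair)
  if (!setequal(sem_tr, sem_te) || length(unique(sem_tr)) != 2L) {
    abort("train and test pairs must share two-label semantics")
  }
  pool <- pool_subset(pool, unique(c(train_pair, test_pair)))
  it <- bootstrap_iterator(pool, cfg$n_iterations, cfg$base_seed,
                           cfg$n_draw, cfg$n_means)
  n_t <- length(pool$times)
  n <- cfg$n_means
  y_train <- rep(sem_tr, each = n)
  y_test <- rep(sem_te, each = n)
  acc <- matrix(0, n_t, cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    pe <- it$draw(i)
    T1 <- pe$classes[[train_pair[1]]]; T2 <- pe$classes[[train_pair[2]]]
    E1 <- pe$classes[[test_pair[1]]]; E2 <- pe$classes[[test_pair[2]]]
    for (t in seq_len(n_t)) {
      mod <- fit_linear_svm(rbind(T1[, , t], T2[, , t]), y_train, cfg$cost)
      pred <- predict(mod, rbind(E1[, , t], E2[, , t]))
      acc[t, i] <- mean(pred == y_test)
    }
  }
  comparison <- sprintf("cross %s->%s",
                        sub("_.*$", "", train_pair[1]),
                        sub("_.*$", "", test_pair[1]))
  new_decoding_timecourse(
    pool$times, rowMeans(acc), comparison, pool$participant_id, cfg,
    iterations = if (cfg$keep_iterations) acc else NULL)
}

#' Decode with replacement labels (shuffle / percept / response controls)
#'
#' Runs the identical bootstrap-SVM machinery after replacing the condition
#' labels of the preprocessed epochs with `new_labels` (two classes). If the
#' relabeling is unbalanced, the majority class is subsampled -- stratified
#' by the original condition labels -- to restore balance, with a warning.
#' With `new_labels` equal to a random permutation of the true labels this
#' is the chance-baseline shuffle control.
#'
#' @param epochs A preprocessed [epoch_set()].
#' @param new_labels Character vector, one label per epoch, two classes.
#' @param cfg A [decode_config()].
#' @return A `decoding_timecourse`.
#' @export
relabel_and_decode <- function(epochs, new_labels, cfg = decode_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(new_labels) != dim(epochs$data)[1]) {
    abort("`new_labels` must have one label per epoch")
  }
  classes <- sort(unique(new_labels))
  if (length(classes) != 2L) abort("`new_labels` must contain two classes")
  counts <- table(new_labels)
  keep <- seq_along(new_labels)
  if (counts[1] != counts[2]) {
    warn("unbalanced relabeling; stratified-subsampling the majority class")
    n_min <- min(counts)
    major <- classes[which.max(counts)]
    keep_major <- with_seed(derive_seed(cfg$base_seed, "rebalance"), {
      idx <- which(new_labels == major)
      strata <- split(idx, epochs$labels[idx])
      quota <- floor(n_min / length(strata))
      picked <- unlist(lapply(strata, function(s) {
        sample(s, min(length(s), quota))
      }), use.names = FALSE)
      short <- n_min - length(picked)
      if (short > 0L) picked <- c(picked, sample(setdiff(idx, picked), short))
      picked
    })
    keep <- sort(c(which(new_labels != major), keep_major))
  }
  sub <- epoch_set(epochs$data[keep, , , drop = FALSE], new_labels[keep],
                   epochs$times, epochs$rate_hz, epochs$participant_id)
  decode_timecourse(build_pool(sub), classes, cfg)
}

#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble::tibble(
    participant = attr(x, "participant"),
    comparison = attr(x, "comparison"),
    time_ms = x$time_ms,
    accuracy = x$accuracy
  )
}

#' @export
glance.decoding_timecourse <- function(x, ...) {
  peak <- which.max(x$accuracy) # ties: earliest timepoint
  tibble::tibble(
    participant = attr(x, "participant"),
    comparison = attr(x, "comparison"),
    peak_accuracy = x$accuracy[peak],
    peak_latency_ms = x$time_ms[peak],
    mean_accuracy = mean(x$accuracy),
    n_iterations = attr(x, "n_iterations"),
    fold_scheme = attr(x, "fold_scheme"),
    seed = attr(x, "seed")
  )
}
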