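#' Build a per-condition sampling pool from preprocessed epochs
#'
#' Partitions an epoch set by condition label into the pool the bootstrap
#' draws from (1260 epochs -> 4 pools of 315 for a default session). Classes
#' carry their member conditions so pooled superclasses (see
#' [pool_conditions()]) can keep bootstrap draws balanced.
#'
#' @param epochs A preprocessed [epoch_set()].
#' @return A `sampling_pool`.
#' @export
build_pool <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] == 0L) abort("cannot build a pool from 0 epochs")
  labs <- sort(unique(epochs$labels))
  counts <- table(epochs$labels)
  if (length(unique(as.integer(counts))) != 1L) {
    abort("per-condition epoch counts are unequal; malformed session")
  }
  classes <- lapply(labs, function(l) {
    member <- list(epochs$data[epochs$labels == l, , , drop = FALSE])
    names(member) <- l
    member
  })
  names(classes) <- labs
  structure(
    list(classes = classes, times = epochs$times,
         participant_id = epochs$participant_id),
    class = "sampling_pool"
  )
}

pool_class_size <- function(pool, class) {
  sum(vapply(pool$classes[[class]], function(m) dim(m)[1], 0L))
}

#' @export
print.sampling_pool <- function(x, ...) {
  sizes <- vapply(names(x$classes), function(cl) pool_class_size(x, cl), 0L)
  cat(sprintf("<sampling_pool> %s: %s\n", x$participant_id,
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Merge a four-condition pool into two pooled superclasses
#'
#' `direction_pooled` opposes TOWARD (CD + IOVD) to AWAY (CD + IOVD);
#' `cue_pooled` opposes CD (toward + away) to IOVD (toward + away). Member
#' conditions are kept separate inside each superclass so that every
#' bootstrap draw takes half its epochs from each member.
#'
#' @param pool A four-condition `sampling_pool`.
#' @param scheme `"direction_pooled"` or `"cue_pooled"`.
#' @return A two-class `sampling_pool`.
#' @export
pool_conditions <- function(pool, scheme = c("direction_pooled",
                                             "cue_pooled")) {
  scheme <- match.arg(scheme)
  need <- c("CD_TOWARD", "CD_AWAY", "IOVD_TOWARD", "IOVD_AWAY")
  if (!setequal(names(pool$classes), need)) {
    abort("pooling requires the four CD/IOVD x TOWARD/AWAY conditions")
  }
  groups <- if (scheme == "direction_pooled") {
    list(TOWARD = c("CD_TOWARD", "IOVD_TOWARD"),
         AWAY = c("CD_AWAY", "IOVD_AWAY"))
  } else {
    list(CD = c("CD_TOWARD", "CD_AWAY"),
         IOVD = c("IOVD_TOWARD", "IOVD_AWAY"))
  }
  pool$classes <- lapply(groups, function(members) {
    out <- lapply(members, function(m) pool$classes[[m]][[m]])
    names(out) <- members
    out
  })
  pool
}

pool_subset <- function(pool, classes) {
  missing <- setdiff(classes, names(pool$classes))
  if (length(missing) > 0L) {
    abort(sprintf("pool has no class(es): %s", paste(missing, collapse = ", ")))
  }
  pool$classes <- pool$classes[classes]
  pool
}

#' Draw one set of mean bootstrapped (pseudo-)epochs
#'
#' For each class, draws `n_means` *disjoint* sets of `n_draw` epochs -- a
#' partition of a random `n_means * n_draw`-epoch subsample of the pool --
#' averages each set pointwise into a pseudo-epoch, then standardises each
#' channel to mean 0 / SD 1 over the whole draw set (one affine transform
#' per electrode, shared by every pseudo-epoch and class, so electrodes get
#' equal weight without any class information entering the transform).
#' Epochs are reused only across iterations (fresh partition per draw call),
#' never within one: pseudo-epochs that shared raw epochs would cluster
#' around the finite pool's noise mean and inflate leave-one-out accuracy
#' above chance on pure noise. Superclasses with several member conditions
#' take `n_draw / n_members` epochs from each member, keeping draws
#' balanced.
#'
#' @param pool A `sampling_pool`.
#' @param n_draw Epochs averaged per pseudo-epoch.
#' @param n_means Pseudo-epochs per class.
#' @param seed RNG seed for this draw.
#' @return A `pseudo_epoch_set`: per class an `n_means x channels x times`
#'   array, already z-scored.
#' @export
draw_mean_epochs <- function(pool, n_draw = 10, n_means = 21, seed = 1L) {
  stopifnot(inherits(pool, "sampling_pool"))
  for (cl in names(pool$classes)) {
    members <- pool$classes[[cl]]
    per_member <- n_draw / length(members)
    if (per_member != round(per_member)) {
      abort("`n_draw` must divide evenly among member conditions")
    }
    for (m in members) {
      if (dim(m)[1] < per_member * n_means) {
        abort(paste0(
          "pool too small: one draw set needs n_means * n_draw disjoint ",
          "epochs per class (reduce `n_means` or `n_draw`)"))
      }
    }
  }
  n_t <- length(pool$times)
  provenance <- list()
  classes <- with_seed(seed, {
    lapply(pool$classes, function(members) {
      per_member <- n_draw / length(members)
      n_ch <- dim(members[[1]])[2]
      out <- array(0, dim = c(n_means, n_ch, n_t))
      # disjoint partition of a random subsample, per member condition
      picks <- lapply(members, function(m) {
        matrix(sample.int(dim(m)[1], per_member * n_means), nrow = n_means)
      })
      names(picks) <- names(members)
      attr(out, "picks") <- picks
      for (j in seq_len(n_means)) {
        acc <- matrix(0, n_ch, n_t)
        for (k in seq_along(members)) {
          for (i in picks[[k]][j, ]) acc <- acc + members[[k]][i, , ]
        }
        out[j, , ] <- acc / n_draw
      }
      out
    })
  })
  provenance <- lapply(classes, attr, "picks")
  classes <- lapply(classes, function(a) { attr(a, "picks") <- NULL; a })
  classes <- zscore_pseudo_set(classes)
  structure(
    list(classes = classes, n_draw = n_draw, n_means = n_means, seed = seed,
         times = pool$times, provenance = provenance),
    class = "pseudo_epoch_set"
  )
}

#' Reproducible stream of bootstrap pseudo-epoch sets
#'
#' Iteration `i` draws with a child seed derived from `(base_seed, i)` by a
#' counter-based scheme, so any iteration can be regenerated independently
#' (and in parallel) while the full stream stays reproducible.
#'
#' @param pool A `sampling_pool`.
#' @param n_iterations Number of iterations in the stream.
#' @param base_seed Stream seed.
#' @param n_draw,n_means Passed to [draw_mean_epochs()].
#' @return A `bootstrap_iterator`: call `$draw(i)` for iteration `i`.
#' @export
bootstrap_iterator <- function(pool, n_iterations, base_seed = 1L,
                               n_draw = 10, n_means = 21) {
  if (n_iterations < 1L) abort("`n_iterations` must be at least 1")
  structure(
    list(
      n_iterations = n_iterations,
      draw = function(i) {
        if (i < 1L || i > n_iterations) abort("iteration index out of range")
        draw_mean_epochs(pool, n_draw, n_means,
                         seed = derive_seed(base_seed, "iteration", i))
      }
    ),
    class = "bootstrap_iterator"
  )
}
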