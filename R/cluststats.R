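#' Assemble a group accuracy matrix
#'
#' Stacks per-participant decoding timecourses for one comparison into the
#' participants x timepoints matrix the group statistics operate on.
#'
#' @param timecourses List of `decoding_timecourse` objects (same time axis).
#' @return Numeric matrix with participants in rows; the time axis is kept
#'   in attribute `"times"`.
#' @export
group_accuracy_matrix <- function(timecourses) {
  if (length(timecourses) < 2L) abort("need at least two participants")
  times <- timecourses[[1]]$time_ms
  mat <- do.call(rbind, lapply(timecourses, function(tc) {
    if (!isTRUE(all.equal(tc$time_ms, times))) {
      abort("timecourses have differing time axes")
    }
    tc$accuracy
  }))
  rownames(mat) <- vapply(timecourses, function(tc) {
    as.character(attr(tc, "participant") %||% "")
  }, "")
  attr(mat, "times") <- times
  mat
}

T_CAP <- 100 # finite stand-in for infinite t at zero variance

#' Pointwise one-sample t statistics against chance
#'
#' `t_k = (mean_k - chance) / (sd_k / sqrt(n))` with `n - 1` degrees of
#' freedom at every timepoint. Zero-variance timepoints yield `+Inf`/`-Inf`
#' sentinels (handled downstream by capping).
#'
#' @param mat Participants x timepoints accuracy matrix.
#' @param chance Chance accuracy (0.5 for pairwise decoding).
#' @return Numeric vector of t values.
#' @export
pointwise_tstats <- function(mat, chance = 0.5) {
  if (!is.matrix(mat) || nrow(mat) < 2L) {
    abort("`mat` must be a matrix with >= 2 participants")
  }
  n <- nrow(mat)
  mu <- colMeans(mat)
  s <- apply(mat, 2, sd)
  t <- (mu - chance) / (s / sqrt(n))
  zero <- s < .Machine$double.eps
  t[zero] <- ifelse(mu[zero] > chance, Inf, ifelse(mu[zero] < chance, -Inf, 0))
  t
}

#' Form temporal clusters of supra-threshold t values
#'
#' Maximal runs of consecutive timepoints whose t statistic exceeds the
#' one-sided critical value at `alpha_forming` (df = n - 1). Each cluster's
#' mass is the sum of its member t values (infinite sentinels capped at 100).
#'
#' @param t Vector of pointwise t statistics.
#' @param n Number of participants (for the critical value).
#' @param alpha_forming Cluster-forming alpha.
#' @param tail `"greater"` (above-chance decoding) or `"two.sided"`.
#' @return Tibble with `start`, `end` (timepoint indices) and `mass`.
#' @export
form_clusters <- function(t, n, alpha_forming = 0.05, tail = "greater") {
  crit <- qt(1 - alpha_forming / (if (tail == "two.sided") 2 else 1),
             df = n - 1)
  over <- if (tail == "two.sided") abs(t) > crit else t > crit
  over[is.na(over)] <- FALSE
  tc <- pmin(pmax(t, -T_CAP), T_CAP)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(
    start = starts[keep],
    end = ends[keep],
    mass = vapply(keep, function(k) {
      sum(if (tail == "two.sided") abs(tc[starts[k]:ends[k]])
          else tc[starts[k]:ends[k]])
    }, 0)
  )
}

#' Sign-flip permutation null of the maximum cluster mass
#'
#' Each permutation flips the sign of every participant's whole
#' `(accuracy - chance)` timecourse independently (the exchangeability unit
#' for a one-sample test), recomputes the t statistics and clusters, and
#' records the maximum cluster mass (0 when no cluster forms).
#'
#' @param mat Participants x timepoints accuracy matrix.
#' @param n_permutations Number of random sign patterns.
#' @param seed RNG seed.
#' @param chance,alpha_forming,tail As in [pointwise_tstats()] /
#'   [form_clusters()].
#' @param exhaustive Enumerate all `2^n` sign patterns instead of sampling
#'   (small n only).
#' @return Numeric vector of maximum cluster masses.
#' @export
permutation_null <- function(mat, n_permutations = 5000, seed = 1L,
                             chance = 0.5, alpha_forming = 0.05,
                             tail = "greater", exhaustive = FALSE) {
  n <- nrow(mat)
  centred <- mat - chance
  max_mass <- function(signs) {
    flipped <- centred * signs
    t <- pointwise_tstats(flipped + chance, chance)
    cl <- form_clusters(t, n, alpha_forming, tail)
    if (nrow(cl) == 0L) 0 else max(cl$mass)
  }
  if (exhaustive) {
    if (n > 20L) abort("exhaustive enumeration is limited to n <= 20")
    patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    return(apply(patterns, 1, max_mass))
  }
  with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      max_mass(sample(c(-1, 1), n, replace = TRUE))
    }, 0)
  })
}

#' Compare observed clusters with the permutation null
#'
#' Cluster p-values use the add-one estimator
#' `p = (1 + #\{null >= mass\}) / (1 + n_permutations)`; a cluster is
#' significant when `p < cluster_alpha`.
#'
#' @param clusters Tibble from [form_clusters()].
#' @param null Vector from [permutation_null()].
#' @param cluster_alpha Cluster-level alpha.
#' @param times Optional time axis (ms) to annotate cluster extents.
#' @return A `cluster_result` tibble: `start`, `end`, `start_ms`, `end_ms`,
#'   `mass`, `p_value`, `significant`.
#' @export
significant_clusters <- function(clusters, null, cluster_alpha = 0.05,
                                 times = NULL) {
  n_perm <- length(null)
  out <- clusters
  out$p_value <- vapply(clusters$mass, function(m) {
    (1 + sum(null >= m)) / (1 + n_perm)
  }, 0)
  out$significant <- out$p_value < cluster_alpha
  if (!is.null(times)) {
    out$start_ms <- times[out$start]
    out$end_ms <- times[out$end]
    out <- out[, c("start", "end", "start_ms", "end_ms", "mass",
                   "p_value", "significant")]
  }
  class(out) <- c("cluster_result", class(tibble::tibble()))
  attr(out, "n_permutations") <- n_perm
  attr(out, "cluster_alpha") <- cluster_alpha
  out
}

#' Cluster-corrected one-sample test of a decoding group matrix
#'
#' Full procedure: pointwise one-sample t tests against chance, temporal
#' clustering at `alpha_forming`, summed-t cluster masses, sign-flip
#' permutation null of the maximum mass, and add-one cluster p-values.
#'
#' @param mat Participants x timepoints accuracy matrix (see
#'   [group_accuracy_matrix()]).
#' @param n_permutations,seed,chance,alpha_forming,cluster_alpha,tail See
#'   the component functions.
#' @return A `cluster_result`; pointwise t values, the null distribution
#'   and settings ride along as attributes.
#' @export
cluster_test <- function(mat, n_permutations = 5000, seed = 1L,
                         chance = 0.5, alpha_forming = 0.05,
                         cluster_alpha = 0.05, tail = "greater") {
  t <- pointwise_tstats(mat, chance)
  cl <- form_clusters(t, nrow(mat), alpha_forming, tail)
  null <- permutation_null(mat, n_permutations, seed, chance,
                           alpha_forming, tail)
  res <- significant_clusters(cl, null, cluster_alpha,
                              times = attr(mat, "times"))
  attr(res, "tstats") <- t
  attr(res, "null") <- null
  attr(res, "times") <- attr(mat, "times")
  attr(res, "settings") <- list(chance = chance,
                                alpha_forming = alpha_forming,
                                cluster_alpha = cluster_alpha, tail = tail,
                                seed = seed)
  res
}

#' Bonferroni-corrected pointwise alternative
#'
#' One-sided pointwise p-values compared against `alpha / n_timepoints`
#' (0.05 / 125 = 4e-4 at defaults).
#'
#' @param mat Participants x timepoints accuracy matrix.
#' @param alpha Family-wise alpha.
#' @param chance Chance level.
#' @return Tibble with `time_index`, `t`, `p_value`, `significant`.
#' @export
bonferroni_pointwise <- function(mat, alpha = 0.05, chance = 0.5) {
  t <- pointwise_tstats(mat, chance)
  n <- nrow(mat)
  p <- pt(t, df = n - 1, lower.tail = FALSE)
  tibble::tibble(
    time_index = seq_along(t),
    time_ms = if (!is.null(attr(mat, "times"))) attr(mat, "times")
              else NA_real_,
    t = t,
    p_value = p,
    significant = p < alpha / length(t)
  )
}

#' @export
tidy.cluster_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x),
    n_significant = sum(x$significant),
    min_p = if (nrow(x) > 0L) min(x$p_value) else NA_real_,
    n_permutations = attr(x, "n_permutations")
  )
}
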