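#' Preprocessing configuration
#'
#' Controls the three preprocessing stages applied to raw epochs: a 30 Hz
#' low-pass Butterworth filter (4th order, applied forward-backward for zero
#' phase), downsampling to 125 Hz by linear interpolation, and per-epoch
#' per-channel z-scoring.
#'
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @param target_rate_hz Downsampled rate, Hz.
#' @param filter_order Butterworth order (of each pass).
#' @param zero_phase Apply the filter forward and backward (no group delay).
#' @param zscore_axis Standardisation contract; only
#'   `"per-channel-over-time"` (within each epoch) is implemented.
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(lowpass_hz = 30, target_rate_hz = 125,
                           filter_order = 4, zero_phase = TRUE,
                           zscore_axis = "per-channel-over-time") {
  if (lowpass_hz >= target_rate_hz / 2) {
    abort("`lowpass_hz` must be below the downsampled Nyquist rate")
  }
  zscore_axis <- match.arg(zscore_axis)
  structure(
    list(lowpass_hz = lowpass_hz, target_rate_hz = target_rate_hz,
         filter_order = filter_order, zero_phase = zero_phase,
         zscore_axis = zscore_axis),
    class = "preproc_config"
  )
}

# Apply an IIR filter b/a along the rows of matrix x (time x series).
# Time-major loop with vectorised updates across series: equivalent to
# signal::filter() per column but far faster for many short series.
iir_filter_matrix <- function(x, b, a) {
  nb <- length(b); na_ <- length(a)
  n_t <- nrow(x); n_s <- ncol(x)
  y <- matrix(0, n_t, n_s)
  for (t in seq_len(n_t)) {
    acc <- b[1] * x[t, ]
    if (nb > 1L && t > 1L) {
      for (i in 2:min(nb, t)) acc <- acc + b[i] * x[t - i + 1L, ]
    }
    if (na_ > 1L && t > 1L) {
      for (j in 2:min(na_, t)) acc <- acc - a[j] * y[t - j + 1L, ]
    }
    y[t, ] <- acc / a[1]
  }
  y
}

# zero-phase filtering with odd-reflection padding at both ends
filtfilt_matrix <- function(x, b, a, n_pad = NULL) {
  n_t <- nrow(x)
  n_pad <- n_pad %||% min(n_t - 1L, 100L)
  top <- 2 * matrix(x[1, ], n_pad, ncol(x), byrow = TRUE) -
    x[(n_pad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(x[n_t, ], n_pad, ncol(x), byrow = TRUE) -
    x[(n_t - 1L):(n_t - n_pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- iir_filter_matrix(xp, b, a)
  y <- iir_filter_matrix(y[nrow(y):1L, , drop = FALSE], b, a)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(n_pad + 1L):(n_pad + n_t), , drop = FALSE]
}

#' Low-pass filter an epoch set
#'
#' Butterworth low-pass (default 4th order, 30 Hz) applied along time to
#' every epoch and channel, with odd-reflection padding; forward-backward by
#' default so the passband has zero phase shift.
#'
#' @param epochs An [epoch_set()].
#' @param cfg A [preproc_config()].
#' @return A filtered `epoch_set` of identical shape.
#' @export
lowpass_filter <- function(epochs, cfg = preproc_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$rate_hz / 2
  if (cfg$lowpass_hz >= nyq) {
    abort("filter cutoff must be below the Nyquist frequency")
  }
  bf <- signal::butter(cfg$filter_order, cfg$lowpass_hz / nyq, type = "low")
  d <- dim(epochs$data)
  # time in rows, (epoch, channel) series in columns; filter epoch blocks
  # to bound working memory on long sessions
  block <- max(1L, floor(2.5e7 / (d[3] * d[2])))
  start <- 1L
  while (start <= d[1]) {
    idx <- start:min(start + block - 1L, d[1])
    x <- matrix(aperm(epochs$data[idx, , , drop = FALSE], c(3, 1, 2)),
                nrow = d[3])
    y <- if (cfg$zero_phase) filtfilt_matrix(x, bf$b, bf$a)
         else iir_filter_matrix(x, bf$b, bf$a)
    epochs$data[idx, , ] <- aperm(array(y, dim = c(d[3], length(idx), d[2])),
                                  c(2, 3, 1))
    start <- start + block
  }
  epochs
}

#' Downsample epochs by linear interpolation
#'
#' Builds the target grid `t_k = t0 + k * 1000 / target_rate_hz` covering the
#' original window (125 samples at 8 ms spacing, -200..792 ms, at defaults)
#' and linearly interpolates each channel's time course onto it; samples that
#' land on raw grid points are copied exactly.
#'
#' @param epochs An [epoch_set()] (normally low-pass filtered first).
#' @param cfg A [preproc_config()].
#' @return A downsampled `epoch_set`.
#' @export
resample_epochs <- function(epochs, cfg = preproc_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (cfg$target_rate_hz > epochs$rate_hz) {
    abort("`target_rate_hz` must not exceed the raw sampling rate")
  }
  d <- dim(epochs$data)
  dur_ms <- d[3] * 1000 / epochs$rate_hz
  n_out <- floor(dur_ms * cfg$target_rate_hz / 1000)
  t_new <- epochs$times[1] + (seq_len(n_out) - 1L) * 1000 / cfg$target_rate_hz
  if (t_new[n_out] > epochs$times[d[3]] + 1e-9) {
    abort("target time grid extends beyond the raw epoch")
  }
  # bracketing indices and weights on the raw grid
  lo <- findInterval(t_new, epochs$times, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), d[3] - 1L)
  w <- (t_new - epochs$times[lo]) / (epochs$times[lo + 1L] - epochs$times[lo])
  w[abs(w) < 1e-9] <- 0
  w[abs(w - 1) < 1e-9] <- 1
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (k in seq_len(n_out)) {
    if (w[k] == 0) {
      out[, , k] <- epochs$data[, , lo[k]]
    } else {
      out[, , k] <- (1 - w[k]) * epochs$data[, , lo[k]] +
        w[k] * epochs$data[, , lo[k] + 1L]
    }
  }
  epochs$data <- out
  epochs$times <- t_new
  epochs$rate_hz <- cfg$target_rate_hz
  epochs
}

#' Z-score epochs per channel over time
#'
#' Within each (pseudo-)epoch, each channel's time course is centred and
#' scaled to unit standard deviation, standardising scale across electrodes
#' without leaking information across epochs. Flat (zero-variance) channels
#' are replaced by zeros with a warning.
#'
#' @param x An [epoch_set()] or a 3-D array (epochs x channels x times).
#' @return Same type as the input.
#' @export
zscore_epochs <- function(x) {
  arr <- if (inherits(x, "epoch_set")) x$data else x
  if (!is.array(arr) || length(dim(arr)) != 3L) {
    abort("`x` must be an epoch_set or 3-D array")
  }
  d <- dim(arr)
  flat <- 0L
  for (e in seq_len(d[1])) {
    m <- arr[e, , , drop = TRUE]
    if (d[2] == 1L) m <- matrix(m, nrow = 1L)
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2) * d[3] / (d[3] - 1L))
    zero <- s < .Machine$double.eps
    flat <- flat + sum(zero)
    s[zero] <- Inf # centred flat channel -> zeros
    arr[e, , ] <- (m - mu) / s
  }
  if (flat > 0L) {
    warn(sprintf("%d flat channel(s) replaced with zeros during z-scoring",
                 flat))
  }
  if (inherits(x, "epoch_set")) {
    x$data <- arr
    x
  } else {
    arr
  }
}

#' Standardise a pseudo-epoch set per channel
#'
#' One affine transform per channel -- subtract the channel's mean and
#' divide by its SD, both computed over all pseudo-epochs, classes and
#' timepoints of the set -- applied identically everywhere. Equalises
#' electrode scales (so every electrode contributes comparably to the
#' classifier) without letting condition information into the transform:
#' a shared per-channel rescaling cannot separate classes.
#'
#' @param classes Named list of `n x channels x times` arrays.
#' @return The standardised list.
#' @export
zscore_pseudo_set <- function(classes) {
  n_ch <- dim(classes[[1]])[2]
  m <- numeric(n_ch); s <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    vals <- unlist(lapply(classes, function(a) a[, ch, ]), use.names = FALSE)
    m[ch] <- mean(vals)
    s[ch] <- sd(vals)
  }
  flat <- s < .Machine$double.eps
  if (any(flat)) {
    warn(sprintf("%d flat channel(s) replaced with zeros during z-scoring",
                 sum(flat)))
    s[flat] <- Inf
  }
  lapply(classes, function(a) {
    out <- a
    for (ch in seq_len(n_ch)) out[, ch, ] <- (a[, ch, ] - m[ch]) / s[ch]
    out
  })
}

#' Full preprocessing chain
#'
#' [lowpass_filter()] then [resample_epochs()]; z-scoring is deliberately
#' applied later, after pseudo-epoch averaging (see [draw_mean_epochs()]).
#'
#' @param epochs An [epoch_set()].
#' @param cfg A [preproc_config()].
#' @return A preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, cfg = preproc_config()) {
  resample_epochs(lowpass_filter(epochs, cfg), cfg)
}
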