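#' Condition-locked component of the synthetic EEG forward model
#'
#' A component is a Hann-windowed spatiotemporal bump: a unit-norm channel
#' topography multiplied by a raised-cosine time course of given onset,
#' duration and amplitude. Its `loading` maps condition labels to signed
#' scale factors, which is what makes conditions decodable: e.g. a cue
#' component loads +1 on CD and -1 on IOVD conditions; a direction component
#' loads +1 on TOWARD and -1 on AWAY within one cue; a shared direction
#' component loads by direction across both cues (one topography, which is
#' what lets a cross-trained decoder transfer).
#'
#' @param name Component name.
#' @param onset_ms,duration_ms Support of the Hann window, ms.
#' @param amplitude_uv Peak amplitude in microvolts.
#' @param loading Named numeric vector, condition label -> signed scale.
#' @param topography Optional unit-norm channel weight vector; if `NULL` a
#'   smooth random topography is drawn (and orthogonalised against the other
#'   components') when the session is generated.
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, onset_ms, duration_ms, amplitude_uv,
                           loading, topography = NULL) {
  assert_scalar_number(duration_ms, "duration_ms", min = 0)
  if (is.null(names(loading)) || any(names(loading) == "")) {
    abort("`loading` must be a named numeric vector (condition -> scale)")
  }
  structure(
    list(name = name, onset_ms = onset_ms, duration_ms = duration_ms,
         amplitude_uv = amplitude_uv, loading = loading,
         topography = topography, window = "hann"),
    class = "component_spec"
  )
}

#' Noise model for synthetic EEG
#'
#' Additive noise is the sum of spatially mixed 1/f ("pink") background
#' activity, a 10 Hz alpha oscillation with a fixed smooth topography and a
#' fresh uniform phase per epoch, and white sensor noise. RMS values are per
#' channel (pink, white) or at the strongest channel (alpha).
#'
#' @param pink_exponent Spectral exponent of the 1/f background.
#' @param pink_rms_uv,alpha_rms_uv,sensor_white_rms_uv RMS amplitudes, uV.
#' @param alpha_freq_hz Alpha frequency, Hz.
#' @param spatial_mixing Mixing weight in `[0, 1)`: each pink-noise sample is
#'   `(1 - s) * own channel + s * random orthogonal mixture` of all channels.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(pink_exponent = 1, pink_rms_uv = 10,
                       alpha_freq_hz = 10, alpha_rms_uv = 5,
                       sensor_white_rms_uv = 2, spatial_mixing = 0.3) {
  for (nm in c("pink_rms_uv", "alpha_rms_uv", "sensor_white_rms_uv")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  structure(
    list(pink_exponent = pink_exponent, pink_rms_uv = pink_rms_uv,
         alpha_freq_hz = alpha_freq_hz, alpha_rms_uv = alpha_rms_uv,
         sensor_white_rms_uv = sensor_white_rms_uv,
         spatial_mixing = spatial_mixing),
    class = "noise_spec"
  )
}

#' Default component set for a condition set
#'
#' The default forward model places a cue-selective component at 120 ms
#' (400 ms long), cue-specific direction components at 320 ms (CD) and
#' 296 ms (IOVD), a direction component with a single topography shared by
#' both cues at 500 ms (250 ms long), and -- for static-disparity sessions --
#' a brief disparity transient at 288 ms. Amplitudes and durations were
#' calibrated once, by pilot simulation, so that group-level cluster onsets
#' recover the injected latencies on the 8 ms analysis grid; mid-window
#' decoding saturates near ceiling under default noise (see the methods
#' vignette).
#'
#' @param condition_set Character vector of condition labels.
#' @return List of [component_spec()]s.
#' @export
default_components <- function(condition_set = c("CD_TOWARD", "CD_AWAY",
                                                 "IOVD_TOWARD", "IOVD_AWAY")) {
  if (setequal(condition_set, c("STATIC_NEAR", "STATIC_FAR"))) {
    return(list(
      component_spec("static_transient", onset_ms = 288, duration_ms = 24,
                     amplitude_uv = 6,
                     loading = c(STATIC_NEAR = 1, STATIC_FAR = -1))
    ))
  }
  list(
    component_spec("cue", onset_ms = 120, duration_ms = 250,
                   amplitude_uv = 16,
                   loading = c(CD_TOWARD = 1, CD_AWAY = 1,
                               IOVD_TOWARD = -1, IOVD_AWAY = -1)),
    component_spec("cd_direction", onset_ms = 320, duration_ms = 150,
                   amplitude_uv = 9,
                   loading = c(CD_TOWARD = 1, CD_AWAY = -1)),
    component_spec("iovd_direction", onset_ms = 296, duration_ms = 150,
                   amplitude_uv = 9,
                   loading = c(IOVD_TOWARD = 1, IOVD_AWAY = -1)),
    component_spec("shared_direction", onset_ms = 500, duration_ms = 250,
                   amplitude_uv = 4,
                   loading = c(CD_TOWARD = 1, CD_AWAY = -1,
                               IOVD_TOWARD = 1, IOVD_AWAY = -1))
  )
}

#' Session specification for the synthetic EEG generator
#'
#' Mirrors the recording protocol the pipeline expects: participants each
#' complete `n_blocks` blocks of `trials_retained_per_block` retained trials
#' (6 x 210 = 1260 epochs by default), with the conditions interleaved at
#' equal frequency; epochs span -200..800 ms around stimulus onset, sampled
#' at `raw_rate_hz` over `n_channels` electrodes.
#'
#' @param n_participants,n_blocks,trials_retained_per_block Design sizes.
#' @param condition_set Condition labels (must divide the trial count).
#' @param raw_rate_hz Raw sampling rate, Hz.
#' @param epoch_window_ms Length-2 epoch window, ms relative to onset.
#' @param n_channels Electrode count.
#' @param components List of [component_spec()]s (defaults via
#'   [default_components()]).
#' @param noise A [noise_spec()].
#' @param master_seed Seed from which the independent label / jitter / noise
#'   / topography RNG streams are derived.
#' @return A `session_spec` list.
#' @export
session_spec <- function(n_participants = 10, n_blocks = 6,
                         trials_retained_per_block = 210,
                         condition_set = c("CD_TOWARD", "CD_AWAY",
                                           "IOVD_TOWARD", "IOVD_AWAY"),
                         raw_rate_hz = 1000,
                         epoch_window_ms = c(-200, 800),
                         n_channels = 64,
                         components = default_components(condition_set),
                         noise = noise_spec(),
                         master_seed = 1L) {
  n_total <- n_blocks * trials_retained_per_block
  if (n_total %% length(condition_set) != 0L) {
    abort("total trial count must divide evenly among conditions")
  }
  dur <- diff(epoch_window_ms)
  if (dur <= 0) abort("`epoch_window_ms` must be an increasing pair")
  for (comp in components) {
    if (comp$onset_ms < epoch_window_ms[1] ||
        comp$onset_ms + comp$duration_ms > epoch_window_ms[2]) {
      abort(sprintf("component '%s' lies outside the epoch window", comp$name))
    }
  }
  structure(
    list(n_participants = n_participants, n_blocks = n_blocks,
         trials_retained_per_block = trials_retained_per_block,
         condition_set = condition_set, raw_rate_hz = raw_rate_hz,
         epoch_window_ms = epoch_window_ms, n_channels = n_channels,
         components = components, noise = noise,
         master_seed = as.integer(master_seed)),
    class = "session_spec"
  )
}

raw_time_axis <- function(spec) {
  step <- 1000 / spec$raw_rate_hz
  seq(spec$epoch_window_ms[1], spec$epoch_window_ms[2] - step, by = step)
}

# smooth random channel vector: white noise convolved over channel index
smooth_channel_vector <- function(n_channels, width = 7) {
  v <- rnorm(n_channels + width - 1)
  k <- rep(1 / width, width)
  as.vector(stats::filter(v, k, sides = 1))[width:(n_channels + width - 1)]
}

# mutually orthogonal unit-norm topographies (Gram-Schmidt over smooth seeds)
make_topographies <- function(n_channels, n_comp) {
  tp <- matrix(0, n_channels, n_comp)
  for (j in seq_len(n_comp)) {
    v <- smooth_channel_vector(n_channels)
    if (j > 1L) {
      prev <- tp[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    tp[, j] <- v / sqrt(sum(v^2))
  }
  tp
}

#' Hann-windowed component waveform
#'
#' Outer product of the component topography with a raised-cosine bump
#' supported on `[onset, onset + duration]`; exactly zero outside and unity
#' at the window midpoint.
#'
#' @param comp A [component_spec()] with a non-`NULL` topography.
#' @param times Time axis in ms.
#' @return `n_channels x length(times)` matrix, uV.
#' @export
generate_component_waveform <- function(comp, times) {
  if (is.null(comp$topography)) {
    abort("component has no topography; supply one or generate a session")
  }
  if (comp$onset_ms < times[1] ||
      comp$onset_ms + comp$duration_ms > times[length(times)] + 1e-9) {
    abort(sprintf("component '%s' lies outside the epoch window", comp$name))
  }
  u <- (times - comp$onset_ms) / comp$duration_ms
  w <- ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
  comp$amplitude_uv * outer(comp$topography, w)
}

# one chunk of additive noise: epochs x channels x times
generate_noise_chunk <- function(m, spec, mix_q, alpha_topo) {
  ns <- spec$noise
  n_ch <- spec$n_channels
  times <- raw_time_axis(spec)
  n_t <- length(times)
  out <- array(0, dim = c(m, n_ch, n_t))
  if (ns$pink_rms_uv > 0) {
    freqs <- spec$raw_rate_hz * pmin(0:(n_t - 1), n_t - (0:(n_t - 1))) / n_t
    s <- c(0, freqs[-1]^(-ns$pink_exponent / 2))
    s <- s / sqrt(mean(s^2)) # unit time-domain variance in expectation
    w <- matrix(rnorm(n_t * m * n_ch), n_t, m * n_ch)
    x <- Re(mvfft(mvfft(w) * s, inverse = TRUE)) / n_t
    x <- x * ns$pink_rms_uv
    a <- array(x, dim = c(n_t, n_ch, m)) # channel fastest within epoch
    smix <- ns$spatial_mixing
    if (smix > 0) {
      mixed <- matrix(aperm(a, c(1, 3, 2)), ncol = n_ch) %*% t(mix_q)
      a <- (1 - smix) * a +
        smix * aperm(array(mixed, dim = c(n_t, m, n_ch)), c(1, 3, 2))
    }
    out <- out + aperm(a, c(3, 2, 1))
  }
  if (ns$alpha_rms_uv > 0) {
    phase <- runif(m, 0, 2 * pi)
    for (j in seq_len(m)) {
      wave <- sin(2 * pi * ns$alpha_freq_hz * times / 1000 + phase[j])
      out[j, , ] <- out[j, , ] +
        sqrt(2) * ns$alpha_rms_uv * outer(alpha_topo, wave)
    }
  }
  if (ns$sensor_white_rms_uv > 0) {
    out <- out + array(rnorm(m * n_ch * n_t, sd = ns$sensor_white_rms_uv),
                       dim = c(m, n_ch, n_t))
  }
  out
}

#' Generate a synthetic EEG session
#'
#' For every participant, builds `n_blocks * trials_retained_per_block`
#' epochs as the sum of (a) each component waveform scaled by its condition
#' loading and a per-participant lognormal amplitude jitter and (b) pink,
#' alpha and white sensor noise. Labels, jitter, topographies and noise use
#' independent RNG streams derived from `master_seed`, so the whole session
#' is reproducible and the signal part is fully determined by the returned
#' ground truth.
#'
#' @param spec A [session_spec()].
#' @param amplitude_scale Multiplier applied to every component amplitude
#'   (`0` gives a pure-noise null session).
#' @return List with `epochs` (list of [epoch_set()] per participant) and
#'   `ground_truth` (components per participant with effective amplitudes,
#'   topography matrix, seeds).
#' @export
generate_session <- function(spec, amplitude_scale = 1) {
  fixed <- session_fixed_effects(spec, amplitude_scale)
  out <- lapply(seq_len(spec$n_participants), function(p) {
    generate_participant(spec, p, fixed = fixed)
  })
  list(
    epochs = lapply(out, `[[`, "epochs"),
    ground_truth = structure(
      list(components = dplyr::bind_rows(lapply(out, `[[`, "ground_truth")),
           topographies = fixed$topo, master_seed = spec$master_seed,
           amplitude_scale = amplitude_scale),
      class = "mid_ground_truth")
  )
}

# session-level draws shared across participants (topographies, alpha
# topography, spatial mixing operator)
session_fixed_effects <- function(spec, amplitude_scale = 1) {
  ms <- spec$master_seed
  n_ch <- spec$n_channels
  comps <- spec$components
  need_topo <- vapply(comps, function(z) is.null(z$topography), logical(1))
  topo <- with_seed(derive_seed(ms, "topography"),
                    make_topographies(n_ch, length(comps)))
  for (j in seq_along(comps)) {
    if (need_topo[j]) {
      comps[[j]]$topography <- topo[, j]
    } else {
      v <- comps[[j]]$topography
      comps[[j]]$topography <- v / sqrt(sum(v^2))
      topo[, j] <- comps[[j]]$topography
    }
  }
  colnames(topo) <- vapply(comps, `[[`, "", "name")
  alpha_topo <- with_seed(derive_seed(ms, "alpha-topo"), {
    v <- smooth_channel_vector(n_ch)
    v / max(abs(v))
  })
  mix_q <- with_seed(derive_seed(ms, "mixing"),
                     qr.Q(qr(matrix(rnorm(n_ch^2), n_ch))))
  list(comps = comps, topo = topo, alpha_topo = alpha_topo, mix_q = mix_q,
       amplitude_scale = amplitude_scale)
}

#' @describeIn generate_session Generate a single participant's epochs
#'   (identical to the corresponding element of the full session; useful for
#'   memory-frugal pipelines that preprocess and discard raw epochs one
#'   participant at a time).
#' @param p Participant index.
#' @param fixed Internal: precomputed session-level effects.
#' @export
generate_participant <- function(spec, p, amplitude_scale = 1,
                                 fixed = NULL) {
  ms <- spec$master_seed
  n_cond <- length(spec$condition_set)
  n_total <- spec$n_blocks * spec$trials_retained_per_block
  times <- raw_time_axis(spec)
  n_t <- length(times)
  n_ch <- spec$n_channels
  fixed <- fixed %||% session_fixed_effects(spec, amplitude_scale)
  comps <- fixed$comps
  labels <- with_seed(derive_seed(ms, "labels", p),
                      sample(rep(spec$condition_set, n_total / n_cond)))
  jitter <- with_seed(derive_seed(ms, "jitter", p),
                      exp(rnorm(length(comps), 0, 0.2)))
  # condition -> signal matrix (channels x times)
  sig <- lapply(spec$condition_set, function(cond) {
    acc <- matrix(0, n_ch, n_t)
    for (j in seq_along(comps)) {
      load <- comps[[j]]$loading[cond]
      if (!is.na(load) && load != 0) {
        acc <- acc + fixed$amplitude_scale * load * jitter[j] *
          generate_component_waveform(comps[[j]], times)
      }
    }
    acc
  })
  names(sig) <- spec$condition_set
  dat <- array(0, dim = c(n_total, n_ch, n_t))
  with_seed(derive_seed(ms, "noise", p), {
    chunk <- max(1L, min(n_total, floor(2e7 / (n_ch * n_t))))
    start <- 1L
    while (start <= n_total) {
      idx <- start:min(start + chunk - 1L, n_total)
      dat[idx, , ] <- generate_noise_chunk(length(idx), spec, fixed$mix_q,
                                           fixed$alpha_topo)
      start <- start + chunk
    }
  })
  for (cond in spec$condition_set) {
    which_e <- which(labels == cond)
    if (any(sig[[cond]] != 0)) {
      add <- aperm(array(sig[[cond]], dim = c(n_ch, n_t, length(which_e))),
                   c(3, 1, 2))
      dat[which_e, , ] <- dat[which_e, , , drop = FALSE] + add
    }
  }
  list(
    epochs = epoch_set(dat, labels, times, spec$raw_rate_hz,
                       participant_id = sprintf("P%02d", p)),
    ground_truth = tibble::tibble(
      participant = sprintf("P%02d", p),
      component = vapply(comps, `[[`, "", "name"),
      onset_ms = vapply(comps, `[[`, 0, "onset_ms"),
      duration_ms = vapply(comps, `[[`, 0, "duration_ms"),
      amplitude_uv = vapply(comps, `[[`, 0, "amplitude_uv") *
        fixed$amplitude_scale,
      jitter = jitter
    )
  )
}

#' Simulate and preprocess a session participant by participant
#'
#' Equivalent to [generate_session()] followed by [preprocess_epochs()] on
#' every participant, but raw (full-rate) epochs are discarded as soon as
#' each participant is preprocessed, keeping peak memory to one participant's
#' raw data.
#'
#' @param spec A [session_spec()].
#' @param cfg A [preproc_config()].
#' @param amplitude_scale Component amplitude multiplier.
#' @return List with `epochs` (preprocessed [epoch_set()]s) and
#'   `ground_truth`.
#' @export
simulate_preprocessed <- function(spec, cfg = preproc_config(),
                                  amplitude_scale = 1) {
  fixed <- session_fixed_effects(spec, amplitude_scale)
  out <- lapply(seq_len(spec$n_participants), function(p) {
    one <- generate_participant(spec, p, fixed = fixed)
    one$epochs <- preprocess_epochs(one$epochs, cfg)
    one
  })
  list(
    epochs = lapply(out, `[[`, "epochs"),
    ground_truth = structure(
      list(components = dplyr::bind_rows(lapply(out, `[[`, "ground_truth")),
           topographies = fixed$topo, master_seed = spec$master_seed,
           amplitude_scale = amplitude_scale),
      class = "mid_ground_truth")
  )
}

#' Generate a pure-noise (null) session
#'
#' As [generate_session()] with all component amplitudes forced to zero;
#' label structure and RNG streams are identical to the matching signal
#' session, so condition means differ only by noise.
#'
#' @param spec A [session_spec()].
#' @return As [generate_session()].
#' @export
generate_null_session <- function(spec) {
  generate_session(spec, amplitude_scale = 0)
}
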