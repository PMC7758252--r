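#' Stimulus specification for random-dot motion-in-depth sequences
#'
#' Describes one trial of a changing-disparity (CD), interocular-velocity-
#' difference (IOVD) or static-disparity random-dot stereogram. Dots live in
#' an annulus and carry a Gaussian luminance profile; depth is signalled
#' either by a linear disparity ramp applied to binocularly paired dots (CD),
#' by equal-and-opposite coherent lateral motion of unpaired dot fields
#' (IOVD), or by a fixed pedestal disparity (static control).
#'
#' Disparity sign convention: positive = uncrossed (far), negative = crossed
#' (near). `TOWARD` motion ramps from the far extreme to the near extreme.
#'
#' @param cue_type One of `"CD"`, `"IOVD"`, `"STATIC"`.
#' @param direction `"TOWARD"`/`"AWAY"` for CD and IOVD, `"NEAR"`/`"FAR"` for
#'   static-disparity sequences.
#' @param duration_ms Trial duration in ms (one full linear ramp).
#' @param eye_frame_rate_hz Per-eye refresh rate in frames/s.
#' @param annulus_inner_deg,annulus_outer_deg Annulus radii, degrees.
#' @param dot_density_per_deg2 Dots per square degree of annulus area.
#' @param dot_sigma_deg Gaussian dot profile sigma, degrees. One "dot width"
#'   is operationalised as `4 * dot_sigma_deg`.
#' @param peak_disparity_arcmin Disparity extreme (arcmin) for CD/static.
#' @param max_monocular_shift_arcmin Extreme of each eye's coherent lateral
#'   shift (arcmin), IOVD only.
#' @param dot_lifetime_ms Dot lifetime (ms) before rebirth, IOVD only.
#' @param strip_height_deg Height of the alternating horizontal strips that
#'   keep the two eyes' IOVD dot fields from overlapping on the retina.
#' @param contrast_ramp_deg Width of the cosine contrast ramp at the annulus
#'   edges (recorded per dot as `contrast_weight`, not rendered).
#' @param seed RNG seed for dot placement.
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(cue_type = c("CD", "IOVD", "STATIC"),
                          direction = c("TOWARD", "AWAY", "NEAR", "FAR"),
                          duration_ms = 250,
                          eye_frame_rate_hz = 60,
                          annulus_inner_deg = 1,
                          annulus_outer_deg = 6,
                          dot_density_per_deg2 = 1,
                          dot_sigma_deg = 0.05,
                          peak_disparity_arcmin = 32,
                          max_monocular_shift_arcmin = 128,
                          dot_lifetime_ms = 50,
                          strip_height_deg = 0.5,
                          contrast_ramp_deg = 0.5,
                          seed = 1L) {
  cue_type <- match.arg(cue_type)
  direction <- match.arg(direction)
  if (annulus_inner_deg >= annulus_outer_deg) {
    abort("`annulus_inner_deg` must be smaller than `annulus_outer_deg`")
  }
  assert_scalar_number(duration_ms, "duration_ms", min = 0)
  assert_scalar_number(eye_frame_rate_hz, "eye_frame_rate_hz", min = 1)
  n_frames <- duration_ms * eye_frame_rate_hz / 1000
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("duration_ms * eye_frame_rate_hz / 1000 must be an integer frame count")
  }
  structure(
    list(
      cue_type = cue_type, direction = direction,
      duration_ms = duration_ms, eye_frame_rate_hz = eye_frame_rate_hz,
      annulus_inner_deg = annulus_inner_deg,
      annulus_outer_deg = annulus_outer_deg,
      dot_density_per_deg2 = dot_density_per_deg2,
      dot_sigma_deg = dot_sigma_deg,
      peak_disparity_arcmin = peak_disparity_arcmin,
      max_monocular_shift_arcmin = max_monocular_shift_arcmin,
      dot_lifetime_ms = dot_lifetime_ms,
      strip_height_deg = strip_height_deg,
      contrast_ramp_deg = contrast_ramp_deg,
      seed = as.integer(seed),
      n_frames = as.integer(round(n_frames))
    ),
    class = "stimulus_spec"
  )
}

n_dots_per_frame <- function(spec) {
  area <- pi * (spec$annulus_outer_deg^2 - spec$annulus_inner_deg^2)
  as.integer(round(spec$dot_density_per_deg2 * area))
}

# uniform sample inside the annulus
sample_annulus <- function(n, ri, ro) {
  r <- sqrt(runif(n, ri^2, ro^2))
  th <- runif(n, 0, 2 * pi)
  list(x = r * cos(th), y = r * sin(th))
}

in_annulus <- function(x, y, ri, ro) {
  r2 <- x^2 + y^2
  r2 >= ri^2 - 1e-12 & r2 <= ro^2 + 1e-12
}

# cosine contrast ramp at both annulus edges
contrast_weight <- function(r, ri, ro, ramp) {
  w <- rep(1, length(r))
  lo <- r < ri + ramp
  hi <- r > ro - ramp
  w[lo] <- 0.5 * (1 - cos(pi * (r[lo] - ri) / ramp))
  w[hi] <- 0.5 * (1 - cos(pi * (ro - r[hi]) / ramp))
  pmin(pmax(w, 0), 1)
}

balanced_polarity <- function(n) {
  sample(rep(c(1L, -1L), length.out = n))
}

# linear ramp inclusive of both endpoints; length-1 case takes the start
linear_ramp <- function(from, to, n) {
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(from)
  seq(from, to, length.out = n)
}

new_stimulus_sequence <- function(spec, dots, ramp) {
  structure(list(spec = spec, dots = dots, ramp = ramp),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> %s %s: %d frames, %d dots/eye/frame\n",
              x$spec$cue_type, x$spec$direction, x$spec$n_frames,
              n_dots_per_frame(x$spec)))
  invisible(x)
}

#' @export
tidy.stimulus_sequence <- function(x, ...) x$dots

# one CD/STATIC frame: fresh binocularly paired dots under disparity d (arcmin)
paired_dot_frame <- function(spec, frame, disparity_arcmin) {
  n <- n_dots_per_frame(spec)
  ri <- spec$annulus_inner_deg; ro <- spec$annulus_outer_deg
  half <- disparity_arcmin / 60 / 2
  x <- numeric(0); y <- numeric(0)
  # rejection-sample base positions so both monocular positions stay in-annulus
  while (length(x) < n) {
    cand <- sample_annulus(2L * (n - length(x)) + 8L, ri, ro)
    ok <- in_annulus(cand$x - half, cand$y, ri, ro) &
      in_annulus(cand$x + half, cand$y, ri, ro)
    x <- c(x, cand$x[ok]); y <- c(y, cand$y[ok])
  }
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  pol <- balanced_polarity(n)
  one_eye <- function(eye, xs) {
    tibble::tibble(
      frame = frame, eye = eye, dot_id = seq_len(n),
      x_deg = xs, y_deg = y, polarity = pol, age = 1L,
      contrast_weight = contrast_weight(sqrt(xs^2 + y^2), ri, ro,
                                        spec$contrast_ramp_deg)
    )
  }
  dplyr::bind_rows(one_eye("left", x - half), one_eye("right", x + half))
}

cd_like_sequence <- function(spec, disparities) {
  dots <- with_seed(spec$seed, {
    purrr::map_dfr(seq_along(disparities), function(f) {
      paired_dot_frame(spec, f, disparities[f])
    })
  })
  ramp <- tibble::tibble(frame = seq_along(disparities),
                         disparity_arcmin = disparities)
  new_stimulus_sequence(spec, dots, ramp)
}

#' Generate a changing-disparity (CD) dot sequence
#'
#' Every frame holds a freshly randomised, binocularly correlated dot field;
#' the two eyes' fields differ only by a horizontal shift of half the frame's
#' disparity per eye. Disparity follows a single linear ramp spanning both
#' extremes (`TOWARD`: +peak to -peak, far to near; `AWAY`: the reverse), so
#' the stimulus-averaged disparity is zero.
#'
#' @param spec A [stimulus_spec()] with `cue_type = "CD"`.
#' @return A `stimulus_sequence`: `$dots` is a tibble with one row per dot
#'   per eye per frame, `$ramp` the per-frame disparity ground truth.
#' @export
make_cd_sequence <- function(spec) {
  if (spec$cue_type != "CD") abort("`spec$cue_type` must be \"CD\"")
  if (!spec$direction %in% c("TOWARD", "AWAY")) {
    abort("CD sequences require direction TOWARD or AWAY")
  }
  p <- spec$peak_disparity_arcmin
  d <- if (spec$direction == "TOWARD") linear_ramp(p, -p, spec$n_frames)
       else linear_ramp(-p, p, spec$n_frames)
  cd_like_sequence(spec, d)
}

#' Generate a static-disparity control sequence
#'
#' Identical dot-refresh behaviour to [make_cd_sequence()] (fresh paired dot
#' fields each frame) but the disparity pedestal is fixed at the near
#' (-peak, crossed) or far (+peak, uncrossed) extreme: stereomotion velocity
#' is zero by construction.
#'
#' @param spec A [stimulus_spec()] with `cue_type = "STATIC"` and direction
#'   `"NEAR"` or `"FAR"`.
#' @return A `stimulus_sequence`.
#' @export
make_static_sequence <- function(spec) {
  if (spec$cue_type != "STATIC") abort("`spec$cue_type` must be \"STATIC\"")
  if (!spec$direction %in% c("NEAR", "FAR")) {
    abort("STATIC sequences require direction NEAR or FAR")
  }
  p <- spec$peak_disparity_arcmin
  d <- rep(if (spec$direction == "FAR") p else -p, spec$n_frames)
  cd_like_sequence(spec, d)
}

# --- IOVD helpers -----------------------------------------------------------

strip_index <- function(y, ro, h) as.integer(floor((y + ro) / h))

# strips counted from the annulus bottom: left eye even, right eye odd
eye_strip_parity <- function(eye) if (eye == "left") 0L else 1L

sample_in_strips <- function(n, spec, eye) {
  ri <- spec$annulus_inner_deg; ro <- spec$annulus_outer_deg
  par <- eye_strip_parity(eye)
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    cand <- sample_annulus(2L * (n - length(x)) + 8L, ri, ro)
    ok <- strip_index(cand$y, ro, spec$strip_height_deg) %% 2L == par
    x <- c(x, cand$x[ok]); y <- c(y, cand$y[ok])
  }
  list(x = x[seq_len(n)], y = y[seq_len(n)])
}

# horizontal chord(s) of the annulus at height y
chords_at <- function(y, ri, ro) {
  xo <- sqrt(max(ro^2 - y^2, 0))
  if (abs(y) >= ri) {
    matrix(c(-xo, xo), ncol = 2)
  } else {
    xi <- sqrt(ri^2 - y^2)
    rbind(c(-xo, -xi), c(xi, xo))
  }
}

# wrap x into the union of annulus chords at y (arc-length wrapping)
wrap_in_chords <- function(x, y, ri, ro) {
  iv <- chords_at(y, ri, ro)
  len <- iv[, 2] - iv[, 1]
  total <- sum(len)
  # position along the concatenated intervals
  s <- NA_real_
  for (k in seq_len(nrow(iv))) {
    if (x >= iv[k, 1] && x <= iv[k, 2]) {
      s <- sum(len[seq_len(k - 1)]) + (x - iv[k, 1])
      break
    }
  }
  if (is.na(s)) {
    # x drifted outside: project via offset from first interval start
    s <- (x - iv[1, 1]) %% total
  } else {
    s <- s %% total
  }
  for (k in seq_len(nrow(iv))) {
    off <- sum(len[seq_len(k - 1)])
    if (s <= off + len[k]) return(iv[k, 1] + (s - off))
  }
  iv[1, 1] + s
}

# Enforce opposite polarity for left/right dots adjacent across a shared
# strip border: every right-eye dot within one dot width of a border that
# has left-eye dots within one dot width of the same border and of its x
# position takes the polarity opposite its nearest such left dot. Polarity
# changes are realised as swaps with off-border right-eye dots, conserving
# the 50:50 balance exactly. Returns the corrected right-eye polarities.
resolve_border_polarity <- function(left, right, spec) {
  dotw <- 4 * spec$dot_sigma_deg
  ro <- spec$annulus_outer_deg; h <- spec$strip_height_deg
  borders <- seq(-ro + h, ro - h, by = h)
  pol <- right$pol
  near_border <- function(y) {
    vapply(y, function(yy) any(abs(yy - borders) <= dotw), logical(1))
  }
  r_near <- near_border(right$y)
  for (j in which(r_near)) {
    bj <- borders[abs(right$y[j] - borders) <= dotw]
    cand <- which(vapply(seq_along(left$y), function(i) {
      any(abs(left$y[i] - bj) <= dotw) && abs(left$x[i] - right$x[j]) <= dotw
    }, logical(1)))
    if (length(cand) == 0L) next
    nearest <- cand[which.min((left$x[cand] - right$x[j])^2 +
                                (left$y[cand] - right$y[j])^2)]
    want <- -left$pol[nearest]
    if (pol[j] != want) {
      k <- which(pol == want & !r_near)[1]
      if (!is.na(k)) {
        pol[k] <- pol[j]
        pol[j] <- want
      } else {
        pol[j] <- want # no balanced swap partner; accept +/-1 imbalance
      }
    }
  }
  pol
}

#' Generate an interocular-velocity-difference (IOVD) dot sequence
#'
#' The two eyes see independent dot fields that translate coherently with
#' equal speed and opposite direction, following a linear shift ramp spanning
#' both extremes of the monocular displacement. Dots live for
#' `dot_lifetime_ms` (3 frames at defaults); deaths are staggered so roughly
#' a third of the dots is reborn at a random position every frame, conserving
#' dot count. Each eye's dots are confined to alternating horizontal strips
#' (left eye even, right eye odd, counted from the annulus bottom) so the
#' fields never coincide on the two retinae; left/right dots adjacent across
#' a shared strip border are forced to opposite contrast polarity to disrupt
#' spurious disparity matches.
#'
#' @param spec A [stimulus_spec()] with `cue_type = "IOVD"`.
#' @return A `stimulus_sequence`; `$ramp` holds the signed per-frame
#'   right-eye shift (`monocular_shift_arcmin`); the left eye's shift is its
#'   negation.
#' @export
make_iovd_sequence <- function(spec) {
  if (spec$cue_type != "IOVD") abort("`spec$cue_type` must be \"IOVD\"")
  if (!spec$direction %in% c("TOWARD", "AWAY")) {
    abort("IOVD sequences require direction TOWARD or AWAY")
  }
  if (spec$strip_height_deg <= 0) abort("`strip_height_deg` must be positive")
  n_f <- spec$n_frames
  m <- spec$max_monocular_shift_arcmin
  # right-eye coherent shift; toward motion mirrors the CD far-to-near ramp
  shift_r <- if (spec$direction == "TOWARD") linear_ramp(m, -m, n_f)
             else linear_ramp(-m, m, n_f)
  ramp <- tibble::tibble(frame = seq_len(n_f),
                         monocular_shift_arcmin = shift_r)
  if (n_f == 0L) {
    return(new_stimulus_sequence(spec, tibble::tibble(
      frame = integer(), eye = character(), dot_id = integer(),
      x_deg = double(), y_deg = double(), polarity = integer(),
      age = integer(), contrast_weight = double()), ramp))
  }
  n <- n_dots_per_frame(spec)
  life <- max(1L, as.integer(round(
    spec$dot_lifetime_ms * spec$eye_frame_rate_hz / 1000)))
  ri <- spec$annulus_inner_deg; ro <- spec$annulus_outer_deg
  dots <- with_seed(spec$seed, {
    state <- list()
    for (eye in c("left", "right")) {
      pos <- sample_in_strips(n, spec, eye)
      state[[eye]] <- list(x = pos$x, y = pos$y,
                           pol = balanced_polarity(n),
                           age = ((seq_len(n) - 1L) %% life) + 1L,
                           id = seq_len(n))
    }
    out <- vector("list", n_f)
    for (f in seq_len(n_f)) {
      if (f > 1L) {
        delta <- (shift_r[f] - shift_r[f - 1]) / 60
        for (eye in c("left", "right")) {
          st <- state[[eye]]
          st$age <- st$age + 1L
          dead <- st$age > life
          d_eye <- if (eye == "right") delta else -delta
          alive <- which(!dead)
          for (i in alive) {
            st$x[i] <- wrap_in_chords(st$x[i] + d_eye, st$y[i], ri, ro)
          }
          n_dead <- sum(dead)
          if (n_dead > 0L) {
            pos <- sample_in_strips(n_dead, spec, eye)
            st$x[dead] <- pos$x; st$y[dead] <- pos$y
            st$age[dead] <- 1L # polarity retained: balance conserved
          }
          state[[eye]] <- st
        }
      }
      state$right$pol <- resolve_border_polarity(state$left, state$right, spec)
      out[[f]] <- dplyr::bind_rows(lapply(c("left", "right"), function(eye) {
        st <- state[[eye]]
        tibble::tibble(
          frame = f, eye = eye, dot_id = st$id, x_deg = st$x, y_deg = st$y,
          polarity = st$pol, age = st$age,
          contrast_weight = contrast_weight(sqrt(st$x^2 + st$y^2), ri, ro,
                                            spec$contrast_ramp_deg))
      }))
    }
    dplyr::bind_rows(out)
  })
  new_stimulus_sequence(spec, dots, ramp)
}

#' Summary statistics of a stimulus sequence
#'
#' Surfaces the defining constants of a generated sequence for validation:
#' disparity extremes and mean, maximum monocular shift, maximum dot age,
#' dot counts and density, and the number of strip indices occupied by both
#' eyes (0 for a well-formed IOVD sequence).
#'
#' @param seq A `stimulus_sequence`.
#' @return A one-row tibble.
#' @export
sequence_stats <- function(seq) {
  if (!inherits(seq, "stimulus_sequence") || nrow(seq$dots) == 0L) {
    abort("`seq` must be a non-empty stimulus_sequence")
  }
  spec <- seq$spec
  has_disp <- "disparity_arcmin" %in% names(seq$ramp)
  dots <- seq$dots
  per_frame <- dots |>
    dplyr::count(.data$frame, .data$eye) |>
    dplyr::pull(.data$n)
  area <- pi * (spec$annulus_outer_deg^2 - spec$annulus_inner_deg^2)
  sidx <- strip_index(dots$y_deg, spec$annulus_outer_deg,
                      spec$strip_height_deg)
  overlap <- length(intersect(unique(sidx[dots$eye == "left"]),
                              unique(sidx[dots$eye == "right"])))
  tibble::tibble(
    mean_disparity_arcmin = if (has_disp) mean(seq$ramp$disparity_arcmin)
                            else NA_real_,
    peak_abs_disparity_arcmin = if (has_disp) max(abs(seq$ramp$disparity_arcmin))
                                else NA_real_,
    max_monocular_shift_arcmin = if (!has_disp)
      max(abs(seq$ramp$monocular_shift_arcmin)) else NA_real_,
    max_dot_age_ms = max(dots$age) * 1000 / spec$eye_frame_rate_hz,
    dots_per_frame = as.integer(round(mean(per_frame))),
    empirical_density = mean(per_frame) / area,
    strip_overlap_count = if (spec$cue_type == "IOVD") overlap else NA_integer_
  )
}

#' Write a stimulus sequence to CSV with a JSON spec sidecar
#'
#' @param seq A `stimulus_sequence`.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_stimulus_sequence <- function(seq, path) {
  write.csv(seq$dots, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  spec <- unclass(seq$spec)
  spec$ramp <- seq$ramp
  jsonlite::write_json(spec, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
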