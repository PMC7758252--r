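test_that("CD disparity ramp spans both extremes with zero mean", {
  cd <- make_cd_sequence(stimulus_spec("CD", "TOWARD", seed = 1))
  expect_equal(nrow(cd$ramp), 15)
  expect_equal(cd$ramp$disparity_arcmin[1], 32)
  expect_equal(cd$ramp$disparity_arcmin[15], -32)
  expect_equal(mean(cd$ramp$disparity_arcmin), 0)
  # odd symmetry about the middle frame
  expect_equal(cd$ramp$disparity_arcmin, -rev(cd$ramp$disparity_arcmin))
  aw <- make_cd_sequence(stimulus_spec("CD", "AWAY", seed = 1))
  expect_equal(aw$ramp$disparity_arcmin, -cd$ramp$disparity_arcmin)
})

test_that("zero duration yields an empty sequence without error", {
  s <- stimulus_spec("CD", "TOWARD", duration_ms = 0)
  cd <- make_cd_sequence(s)
  expect_equal(nrow(cd$dots), 0)
  expect_equal(nrow(cd$ramp), 0)
  expect_error(sequence_stats(cd), "non-empty")
})

test_that("CD frames are binocularly paired up to the disparity shift", {
  cd <- make_cd_sequence(stimulus_spec("CD", "TOWARD", seed = 5))
  for (f in c(1, 8, 15)) {
    l <- dplyr::filter(cd$dots, frame == f, eye == "left") |>
      dplyr::arrange(dot_id)
    r <- dplyr::filter(cd$dots, frame == f, eye == "right") |>
      dplyr::arrange(dot_id)
    d_deg <- cd$ramp$disparity_arcmin[f] / 60
    expect_equal(r$y_deg, l$y_deg)
    expect_equal(r$x_deg - l$x_deg, rep(d_deg, nrow(l)))
    expect_equal(r$polarity, l$polarity)
  }
  # no temporal correlation: fresh positions each frame
  f1 <- dplyr::filter(cd$dots, frame == 1, eye == "left")$x_deg
  f2 <- dplyr::filter(cd$dots, frame == 2, eye == "left")$x_deg
  expect_gt(sum(abs(f1 - f2)), 1e-6)
})

test_that("all dots stay inside the annulus over many seeds", {
  for (seed in 1:100) {
    cd <- make_cd_sequence(stimulus_spec("CD",
                                         if (seed %% 2) "TOWARD" else "AWAY",
                                         seed = seed))
    r <- with(cd$dots, sqrt(x_deg^2 + y_deg^2))
    expect_true(all(r >= 1 - 1e-9 & r <= 6 + 1e-9))
  }
  for (seed in 1:15) {
    io <- make_iovd_sequence(stimulus_spec("IOVD", "TOWARD", seed = seed))
    r <- with(io$dots, sqrt(x_deg^2 + y_deg^2))
    expect_true(all(r >= 1 - 1e-9 & r <= 6 + 1e-9))
  }
})

test_that("polarities balance 50:50 per eye and frame", {
  for (seq_ in list(make_cd_sequence(stimulus_spec("CD", "TOWARD", seed = 3)),
                    make_iovd_sequence(stimulus_spec("IOVD", "AWAY",
                                                     seed = 3)))) {
    bal <- seq_$dots |>
      dplyr::group_by(frame, eye) |>
      dplyr::summarise(imb = abs(sum(polarity)), .groups = "drop")
    expect_true(all(bal$imb <= 1))
  }
})

test_that("IOVD kinematics: shift ramp, lifetime, rebirth, strips", {
  io <- make_iovd_sequence(stimulus_spec("IOVD", "TOWARD", seed = 11))
  expect_equal(max(abs(io$ramp$monocular_shift_arcmin)), 128)
  expect_equal(io$ramp$monocular_shift_arcmin[1], 128)
  expect_equal(io$ramp$monocular_shift_arcmin[15], -128)
  # ages never exceed the 3-frame (50 ms) lifetime; dot count conserved
  expect_lte(max(io$dots$age), 3)
  counts <- dplyr::count(io$dots, frame, eye)
  expect_true(all(counts$n == 110))
  # staggered deaths: about a third of dots reborn each frame
  reborn <- io$dots |>
    dplyr::filter(frame > 1, age == 1) |>
    dplyr::count(frame, eye)
  expect_true(all(reborn$n %in% c(36, 37)))
  # strip assignment: the two eyes' strip-index sets are disjoint
  sidx <- floor((io$dots$y_deg + 6) / 0.5)
  expect_length(intersect(unique(sidx[io$dots$eye == "left"]),
                          unique(sidx[io$dots$eye == "right"])), 0)
  expect_true(all(sidx[io$dots$eye == "left"] %% 2 == 0))
  expect_true(all(sidx[io$dots$eye == "right"] %% 2 == 1))
})

test_that("IOVD eyes move with equal and opposite coherent shifts", {
  io <- make_iovd_sequence(stimulus_spec("IOVD", "TOWARD", seed = 19))
  # surviving dots move by the per-frame ramp increment, sign by eye
  delta_ramp <- diff(io$ramp$monocular_shift_arcmin) / 60
  wide <- io$dots |>
    dplyr::arrange(frame) |>
    dplyr::group_by(eye, dot_id) |>
    dplyr::mutate(dx = x_deg - dplyr::lag(x_deg),
                  survived = age > 1) |>
    dplyr::ungroup() |>
    dplyr::filter(frame > 1, survived, abs(dx) < 1) # exclude wrapped dots
  for (f in unique(wide$frame)) {
    sub <- wide[wide$frame == f, ]
    dl <- median(sub$dx[sub$eye == "left"])
    dr <- median(sub$dx[sub$eye == "right"])
    expect_equal(dr, delta_ramp[f - 1], tolerance = 1e-9)
    expect_equal(dl, -delta_ramp[f - 1], tolerance = 1e-9)
  }
})

test_that("border-adjacent left/right dot pairs carry opposite polarity", {
  for (seed in 1:5) {
    io <- make_iovd_sequence(stimulus_spec("IOVD", "AWAY", seed = seed))
    dotw <- 4 * 0.05
    borders <- seq(-6 + 0.5, 6 - 0.5, by = 0.5)
    for (f in unique(io$dots$frame)) {
      l <- io$dots[io$dots$frame == f & io$dots$eye == "left", ]
      r <- io$dots[io$dots$frame == f & io$dots$eye == "right", ]
      for (j in seq_len(nrow(r))) {
        bj <- borders[abs(r$y_deg[j] - borders) <= dotw]
        if (length(bj) == 0) next
        cand <- which(vapply(seq_len(nrow(l)), function(i) {
          any(abs(l$y_deg[i] - bj) <= dotw) &&
            abs(l$x_deg[i] - r$x_deg[j]) <= dotw
        }, logical(1)))
        if (length(cand) == 0) next
        nearest <- cand[which.min((l$x_deg[cand] - r$x_deg[j])^2 +
                                    (l$y_deg[cand] - r$y_deg[j])^2)]
        expect_equal(r$polarity[j], -l$polarity[nearest])
      }
    }
  }
})

test_that("static sequences hold a constant disparity pedestal", {
  far <- make_static_sequence(stimulus_spec("STATIC", "FAR", seed = 2))
  expect_true(all(far$ramp$disparity_arcmin == 32))
  expect_equal(var(far$ramp$disparity_arcmin), 0)
  expect_true(all(diff(far$ramp$disparity_arcmin) == 0))
  near <- make_static_sequence(stimulus_spec("STATIC", "NEAR", seed = 2))
  expect_true(all(near$ramp$disparity_arcmin == -32))
})

test_that("sequence_stats reports the defining constants", {
  cd <- make_cd_sequence(stimulus_spec("CD", "TOWARD", seed = 4))
  st <- sequence_stats(cd)
  expect_equal(st$dots_per_frame, round(pi * (36 - 1))) # 110 dots
  expect_equal(st$empirical_density, 1, tolerance = 0.01)
  expect_equal(st$peak_abs_disparity_arcmin, 32)
  expect_equal(st$mean_disparity_arcmin, 0)
  io <- sequence_stats(make_iovd_sequence(stimulus_spec("IOVD", "TOWARD",
                                                        seed = 4)))
  expect_equal(io$max_monocular_shift_arcmin, 128)
  expect_equal(io$max_dot_age_ms, 50)
  expect_equal(io$strip_overlap_count, 0L)
})

test_that("sequence writer emits a CSV plus JSON sidecar", {
  cd <- make_cd_sequence(stimulus_spec("CD", "AWAY", seed = 9))
  path <- file.path(withr::local_tempdir(), "cd.csv")
  write_stimulus_sequence(cd, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(cd$dots))
  expect_named(back, names(cd$dots))
  side <- jsonlite::fromJSON(sub("csv$", "json", path))
  expect_equal(side$peak_disparity_arcmin, 32)
  expect_equal(side$cue_type, "CD")
})

test_that("invalid configurations are rejected", {
  expect_error(make_cd_sequence(stimulus_spec("IOVD", "TOWARD")), "CD")
  expect_error(make_cd_sequence(stimulus_spec("CD", "NEAR")), "TOWARD or AWAY")
  expect_error(make_iovd_sequence(stimulus_spec("IOVD", "FAR")),
               "TOWARD or AWAY")
  expect_error(make_static_sequence(stimulus_spec("STATIC", "TOWARD")),
               "NEAR or FAR")
  expect_error(make_iovd_sequence(stimulus_spec("IOVD", "TOWARD",
                                                strip_height_deg = 0)),
               "strip_height")
  expect_error(stimulus_spec("CD", "TOWARD", annulus_inner_deg = 7),
               "smaller")
  expect_error(stimulus_spec("CD", "TOWARD", duration_ms = 37), "integer")
})
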