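test_that("step segmentation tiles events and excludes turn windows", {
  w <- make_walk(duration = 60, seed = 51)   # turns at 20 s and 40 s
  ev <- postprocess(w$truth_labels, w$prec)

  all_w <- segment_steps(ev, w$prec, exclude_turns = FALSE)
  expect_equal(nrow(all_w), nrow(ev) - 1)
  expect_true(all(all_w$end_frame > all_w$start_frame))

  kept <- segment_steps(ev, w$prec, exclude_turns = TRUE)
  expect_lt(nrow(kept), nrow(all_w))
  # the mean-rotation-rate criterion removes every window reaching the
  # core of a turn bout (edge windows may retain sub-half overlap)
  turn_cores <- rbind(c(20.3, 21.7), c(40.3, 41.7))
  for (i in seq_len(nrow(kept))) {
    s <- kept$start_time[i]
    e <- s + kept$duration[i]
    expect_false(any(s < turn_cores[, 2] & e > turn_cores[, 1]))
  }
  # and windows fully inside a bout are always flagged
  inside <- all_w$start_time >= 20 &
    all_w$start_time + all_w$duration <= 22
  expect_true(all(all_w$in_turn[inside]))

  ten <- foot_strike_events(seq(10L, 100L, by = 10L),
                            seq(9, 99, by = 10) / 50)
  rec10 <- make_channel_rec(rnorm(120))
  expect_equal(nrow(segment_steps(ten, rec10, exclude_turns = FALSE)), 9)
  two <- foot_strike_events(c(10L, 20L), c(9, 19) / 50)
  expect_error(segment_steps(two, rec10), "at least 3")
})

test_that("temporal features implement the symmetry index exactly", {
  mkw <- function(durs, sides) {
    structure(data.frame(start_frame = 1L, end_frame = 2L,
                         start_time = 0, duration = durs, side = sides,
                         in_turn = FALSE),
              class = c("step_windows", "data.frame"))
  }
  # perfectly symmetric: SI = 0, cadence = 60/0.5 = 120
  tf <- temporal_features(mkw(c(0.5, 0.5, 0.5),
                              c("left", "right", "left")))
  expect_equal(unname(tf[, "symmetry_index"]), c(0, 0, 0))
  expect_equal(unname(tf[1, "cadence"]), 120)
  expect_equal(unname(tf[1, "stride_time"]), 1)

  # tR = 0.55, tL = 0.45 gives SI = 20
  tf2 <- temporal_features(mkw(c(0.55, 0.45), c("right", "left")))
  expect_equal(unname(tf2[1, "symmetry_index"]), 20)
  expect_equal(unname(tf2[1, "step_time_right"]), 0.55)
  expect_equal(unname(tf2[1, "step_time_left"]), 0.45)

  # unknown sides fall back to pseudo-sides with a warning
  expect_warning(tf3 <- temporal_features(mkw(c(0.5, 0.6),
                                              c("unknown", "unknown"))),
                 "pseudo-sides")
  expect_true(isTRUE(attr(tf3, "pseudo_sides")))
})

test_that("window statistics match hand arithmetic", {
  n <- 40
  df <- data.frame(time_s = (0:(n - 1)) / 50,
                   lin_ml = rep(c(-1, 1), n / 2),
                   lin_ap = rnorm(n), lin_vert = rnorm(n),
                   tilt_deg = -2.5, rotation_deg = rnorm(n),
                   obliquity_deg = rnorm(n))
  rec <- imu_recording(df, sample_rate = 50)
  w <- list(start_frame = 1L, end_frame = n + 1L)
  s <- window_stats(rec, w)
  expect_length(s, 27)

  expect_equal(unname(s["mean_ml"]), 0)
  expect_equal(unname(s["rms_ml"]), 1)
  expect_equal(unname(s[c("min_ml", "max_ml")]), c(-1, 1))

  # constant channel: mean = value, sd = 0, range = 0, rms = |value|
  expect_equal(unname(s["mean_tilt"]), -2.5)
  expect_equal(unname(s["sd_tilt"]), 0)
  expect_equal(unname(s["range_tilt"]), 0)
  expect_equal(unname(s["rms_tilt"]), 2.5)
  expect_error(window_stats(rec, list(start_frame = 5L, end_frame = 5L)),
               "empty")
})

test_that("spectral features separate odd and even harmonics", {
  n <- 128
  t <- (0:(n - 1)) / 50
  f1 <- 50 * 8 / 256            # bin-aligned at the step frequency
  base <- data.frame(time_s = t, lin_ml = 0, lin_ap = 0, lin_vert = 0,
                     tilt_deg = 0, rotation_deg = 0, obliquity_deg = 0)
  w <- list(start_frame = 1L, end_frame = n + 1L)

  base$lin_ap <- sin(2 * pi * f1 * t)
  rec1 <- imu_recording(base, sample_rate = 50)
  sp1 <- spectral_features(rec1, w, step_freq = f1)
  expect_length(sp1, 30)
  expect_lt(unname(sp1["reoh_ap"]), 0.05)     # fundamental is odd

  base$lin_ap <- sin(2 * pi * 2 * f1 * t)
  rec2 <- imu_recording(base, sample_rate = 50)
  sp2 <- spectral_features(rec2, w, step_freq = f1)
  expect_gt(unname(sp2["reoh_ap"]), 0.95)     # all power even

  # an impulse filling the FFT length has a flat magnitude spectrum
  # away from DC: peak distinction ~ 0
  n2 <- 256
  base2 <- data.frame(time_s = (0:(n2 - 1)) / 50, lin_ml = 0,
                      lin_ap = c(1, rep(0, n2 - 1)), lin_vert = 0,
                      tilt_deg = 0, rotation_deg = 0, obliquity_deg = 0)
  rec3 <- imu_recording(base2, sample_rate = 50)
  w2 <- list(start_frame = 1L, end_frame = n2 + 1L)
  sp3 <- spectral_features(rec3, w2, step_freq = f1)
  expect_lt(unname(sp3["fft_peak_distinction_ap"]), 0.05)

  expect_error(spectral_features(rec3, w2, step_freq = 0), "positive")
  expect_error(
    spectral_features(rec3, list(start_frame = 1L, end_frame = 3L), f1),
    ">= 4")
})

test_that("feature table has the 62-column registry and scales sanely", {
  w <- make_walk(duration = 30, seed = 53)
  ev <- postprocess(w$truth_labels, w$prec)
  tab <- step_features(w$prec, ev)
  expect_true(all(feature_registry() %in% names(tab)))
  expect_length(feature_registry(), 62)
  expect_gt(nrow(tab), 10)

  # manual vs identical automated events give identical tables
  tab2 <- step_features(w$prec, ev)
  expect_identical(tab, tab2)

  # noise-free symmetric walk: symmetry index ~ 0 (frame quantization
  # bounds it near 4%)
  ws <- make_walk(duration = 30, noise_sd = 0, seed = 55)
  tabs <- step_features(ws$prec, postprocess(ws$truth_labels, ws$prec))
  expect_lt(max(tabs$symmetry_index), 5)

  # doubling a channel doubles covariant features, leaves invariant ones
  rec2 <- w$prec
  rec2$lin_ap <- 2 * rec2$lin_ap
  tabd <- step_features(rec2, ev)
  for (f in c("min_ap", "max_ap", "mean_ap", "sd_ap", "rms_ap",
              "fft_max_ap", "fft_sd_ap", "fft_quartile_ap")) {
    expect_equal(tabd[[f]], 2 * tab[[f]], tolerance = 1e-9)
  }
  for (f in c("reoh_ap", "fft_peak_distinction_ap")) {
    expect_equal(tabd[[f]], tab[[f]], tolerance = 1e-9)
  }
})

test_that("participant aggregation gives 248 ordered, coherent values", {
  w <- make_walk(duration = 30, seed = 57)
  tab <- step_features(w$prec, postprocess(w$truth_labels, w$prec))
  pv <- aggregate_participant(tab, fall_risk = TRUE, "P001")
  expect_length(pv$features, 248)
  expect_identical(names(pv$features), participant_registry())

  # min <= mean <= max and sd >= 0 for every feature
  for (f in feature_registry()) {
    expect_lte(pv$features[[paste0(f, "_min")]],
               pv$features[[paste0(f, "_mean")]])
    expect_lte(pv$features[[paste0(f, "_mean")]],
               pv$features[[paste0(f, "_max")]])
    expect_gte(pv$features[[paste0(f, "_sd")]], 0)
  }

  # two rows with values 1 and 3: min 1, max 3, mean 2, sd sqrt(2)
  toy <- tab[1:2, ]
  toy$cadence <- c(1, 3)
  pv2 <- aggregate_participant(toy, FALSE, "P002")
  expect_equal(unname(pv2$features[c("cadence_min", "cadence_max",
                                     "cadence_mean", "cadence_sd")]),
               c(1, 3, 2, sqrt(2)))

  # identical rows: sd 0 and min = max = mean
  same <- tab[c(1, 1), ]
  pv3 <- aggregate_participant(same, FALSE, "P003")
  expect_true(all(pv3$features[paste0(feature_registry(), "_sd")] == 0))

  expect_error(aggregate_participant(tab[1, ], FALSE), "at least 2")
})
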