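test_that("rule-based labelling recovers truth and demands peak order", {
  w <- make_walk(duration = 30, noise_sd = 0, seed = 11)
  ev <- label_rule_based(w$prec)
  m <- match_events(ev, w$events, tolerance_frames = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  # flat signals give an empty list, not an error
  flat <- imu_recording(data.frame(time_s = (0:299) / 50,
                                   lin_ap = 0, lin_vert = 0),
                        sample_rate = 50)
  expect_equal(nrow(label_rule_based(flat, lock = 10)), 0)

  # an AP peak with no following vertical peak is not an event
  t <- (0:499) / 50
  ap <- numeric(500)
  vert <- numeric(500)
  centres <- c(100, 150, 200, 250, 300, 350)
  for (f in centres) {
    ap <- ap + 2 * exp(-((t - t[f])^2) / (2 * 0.05^2))
  }
  for (f in setdiff(centres, 250)) {      # one strike loses its vert peak
    vert <- vert + 3 * exp(-((t - t[f] - 0.06)^2) / (2 * 0.05^2))
  }
  rec <- imu_recording(data.frame(time_s = t, lin_ap = ap,
                                  lin_vert = vert), sample_rate = 50)
  ev2 <- label_rule_based(rec, lock = 10)
  expect_setequal(ev2$frame, setdiff(centres, 250))
})

test_that("locking period tracks the dominant step period with clamping", {
  mk <- function(x) make_channel_rec(x)
  t <- (0:499) / 50
  expect_equal(compute_locking_period(mk(sin(2 * pi * 2 * t))), 12L)
  expect_equal(compute_locking_period(mk(sin(2 * pi * 1 * t))), 25L)
  set.seed(21)
  expect_equal(compute_locking_period(mk(rnorm(500))), 10L)
  # a very slow oscillation clamps at the upper bound
  expect_equal(compute_locking_period(mk(sin(2 * pi * 0.6 * t))), 35L)
  expect_error(compute_locking_period(mk(sin(t[1:100]))), "5 s")
})

test_that("collapse_duplicates keeps the AP peak of each run", {
  labels <- rep(0L, 400)
  labels[240:242] <- 1L
  labels[100] <- 1L
  ap <- rnorm(400, 0, 0.01)
  ap[240:242] <- c(0.5, 2, 1)
  ev <- collapse_duplicates(frame_labels(labels), ap)
  expect_equal(ev$frame, c(100L, 241L))

  # no consecutive 1s: identity; all-zero: empty
  iso <- rep(0L, 100); iso[c(10, 30, 77)] <- 1L
  expect_equal(collapse_duplicates(frame_labels(iso), rnorm(100))$frame,
               c(10L, 30L, 77L))
  expect_equal(nrow(collapse_duplicates(frame_labels(rep(0L, 50)),
                                        rnorm(50))), 0)

  # never increases event count and is idempotent (property)
  set.seed(5)
  for (i in 1:20) {
    lab <- frame_labels(rbinom(300, 1, 0.1))
    ap_i <- rnorm(300)
    ev1 <- collapse_duplicates(lab, ap_i)
    expect_lte(nrow(ev1), sum(lab))
    ev2 <- collapse_duplicates(events_to_labels(ev1, 300), ap_i)
    expect_equal(ev2$frame, ev1$frame)
  }
})

test_that("insert_missed fills qualifying gaps at AP local maxima", {
  ap <- rep(0, 400)
  ap[239:241] <- c(0.5, 1, 0.5)
  ev <- foot_strike_events(c(100L, 150L, 330L), c(99, 149, 329) / 50)
  out <- insert_missed(ev, ap, lock = 20)
  expect_equal(out$frame, c(100L, 150L, 240L, 330L))

  # uniform spacing stays unchanged; < 3 events stay unchanged
  u <- foot_strike_events(seq(50L, 350L, by = 50L),
                          seq(49, 349, by = 50) / 50)
  expect_equal(insert_missed(u, rnorm(400), 20)$frame, u$frame)
  two <- foot_strike_events(c(10L, 300L), c(9, 299) / 50)
  expect_equal(insert_missed(two, rnorm(400), 20)$frame, two$frame)

  # never removes events (property over degraded walks)
  w <- make_walk(duration = 30, seed = 13)
  lock <- compute_locking_period(w$prec)
  for (s in 1:5) {
    deg <- degrade_labels(w$truth_labels, drop_rate = 0.2, seed = s)
    ev_d <- collapse_duplicates(deg, w$prec$lin_ap, w$prec$time_s)
    out_d <- insert_missed(ev_d, w$prec$lin_ap, lock,
                           time_s = w$prec$time_s)
    expect_true(all(ev_d$frame %in% out_d$frame))
    expect_true(all(diff(out_d$frame) > 0))
  }
})

test_that("postprocess repairs degraded labels and is clean on truth", {
  w <- make_walk(duration = 60, noise_sd = 0.2, seed = 17)

  # clean truth labels come back unchanged, with alternating sides
  ev <- postprocess(w$truth_labels, w$prec)
  expect_equal(ev$frame, w$events$frame)
  expect_equal(ev$side, w$events$side)

  # degraded labels are repaired to >= 90% of truth within 2 frames
  deg <- degrade_labels(w$truth_labels, drop_rate = 0.1,
                        duplicate_rate = 0.3, seed = 23)
  rep_ev <- postprocess(deg, w$prec)
  expect_gte(match_events(rep_ev, w$events, 2)$recall, 0.9)

  # events stay strictly increasing and >= lock apart (property)
  lock <- compute_locking_period(w$prec)
  for (s in 1:5) {
    d <- degrade_labels(w$truth_labels, 0.1, 0.3, 1L, seed = s)
    e <- postprocess(d, w$prec)
    expect_true(all(diff(e$frame) >= lock))
  }

  # empty labels give empty events
  empty <- frame_labels(rep(0L, nrow(w$prec)))
  expect_equal(nrow(postprocess(empty, w$prec)), 0)

  # rule-based labelling and postprocessed truth agree on clean walks
  wn <- make_walk(duration = 30, noise_sd = 0, seed = 19)
  rb <- label_rule_based(wn$prec)
  pt <- postprocess(wn$truth_labels, wn$prec)
  expect_equal(rb$frame, pt$frame)
})

test_that("detection metrics are exact in strict and tolerance modes", {
  truth <- frame_labels(c(0, 1, 0, 0, 1, 0, 0, 0, 1, 0))
  expect_equal(unlist(detection_metrics(truth, truth)), c(
    accuracy = 1, sensitivity = 1, specificity = 1))

  zero <- frame_labels(rep(0L, 10))
  m <- detection_metrics(zero, truth)
  expect_equal(m$accuracy, 7 / 10)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)

  # +2 frame shift is perfect under the 2-frame tolerance
  shifted <- frame_labels(c(0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1))
  truth11 <- frame_labels(c(0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0))
  expect_equal(detection_metrics(shifted, truth11)$sensitivity, 0)
  mt <- detection_metrics(shifted, truth11, tolerance_frames = 2)
  expect_equal(mt$sensitivity, 1)
  expect_equal(mt$accuracy, 1)

  expect_error(detection_metrics(zero, truth11), "equal length")
})
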