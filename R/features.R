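# Step segmentation and the 62-feature-per-step registry: temporal,
# descriptive and spectral descriptors, aggregated to 248 values per
# participant.

#' Segment a walk into step windows
#'
#' One half-open window `[start, end)` per consecutive event pair. A
#' window is flagged `in_turn` when its mean absolute vertical-axis
#' rotation rate exceeds `turn_threshold` (from the `gz` gyro channel,
#' or the differentiated rotation angle when `gz` is absent); flagged
#' windows are removed when `exclude_turns` is set.
#'
#' @param events [foot_strike_events()] with at least 3 events.
#' @param rec The uniform [imu_recording()] the events index into.
#' @param exclude_turns Drop turn windows (default `TRUE`).
#' @param turn_threshold Rotation-rate threshold in degrees/s
#'   (default 45).
#' @return A `step_windows` data frame: `start_frame`, `end_frame`,
#'   `start_time`, `duration` (s), `side` (of the starting event),
#'   `in_turn`.
#' @export
segment_steps <- function(events, rec, exclude_turns = TRUE,
                          turn_threshold = 45) {
  if (nrow(events) < 3) {
    stop("step segmentation needs at least 3 foot-strike events")
  }
  fs <- sample_rate(rec)
  if (is.null(fs)) stop("recording must be resampled to a uniform rate")
  n_ev <- nrow(events)
  rot_rate <- if (!is.null(rec$gz)) {
    abs(rec$gz) * 180 / pi
  } else if (!is.null(rec$rotation_deg)) {
    abs(c(0, diff(rec$rotation_deg))) * fs
  } else {
    rep(0, nrow(rec))
  }
  w <- data.frame(
    start_frame = events$frame[-n_ev],
    end_frame = events$frame[-1],
    start_time = events$time_s[-n_ev],
    duration = diff(events$time_s),
    side = events$side[-n_ev],
    stringsAsFactors = FALSE
  )
  w$in_turn <- vapply(seq_len(nrow(w)), function(i) {
    mean(rot_rate[w$start_frame[i]:(w$end_frame[i] - 1L)]) >
      turn_threshold
  }, logical(1))
  if (exclude_turns) w <- w[!w$in_turn, , drop = FALSE]
  rownames(w) <- NULL
  structure(w, class = c("step_windows", "data.frame"))
}

#' Per-step temporal features
#'
#' For each window: cadence (60 / step time, steps/min), right and left
#' step times (the window's own duration on its starting side, its
#' neighbouring window's duration on the other side), stride time (sum
#' of the two), and the symmetry index
#' \eqn{|t_R - t_L| / (0.5 (t_R + t_L)) \times 100}. When sides are
#' unassigned, alternating pseudo-sides are used and the result carries
#' a `pseudo_sides` attribute.
#'
#' @param windows A `step_windows` data frame (all physical steps, in
#'   order — segment with `exclude_turns = FALSE` and subset after).
#' @return Numeric matrix, one row per window, columns `cadence`,
#'   `step_time_right`, `step_time_left`, `stride_time`,
#'   `symmetry_index`.
#' @export
temporal_features <- function(windows) {
  n <- nrow(windows)
  if (n == 0) stop("no step windows")
  sides <- windows$side
  pseudo <- FALSE
  if (any(sides == "unknown")) {
    warning("unassigned sides: attributing step times to alternating ",
            "pseudo-sides")
    sides <- rep(c("left", "right"), length.out = n)
    pseudo <- TRUE
  }
  d <- windows$duration
  # neighbour = following window; the last window falls back to the
  # preceding one
  d_other <- c(d[-1], if (n > 1) d[n - 1] else d[1])
  t_r <- ifelse(sides == "right", d, d_other)
  t_l <- ifelse(sides == "left", d, d_other)
  out <- cbind(
    cadence = 60 / d,
    step_time_right = t_r,
    step_time_left = t_l,
    stride_time = d + d_other,
    symmetry_index = abs(t_r - t_l) / (0.5 * (t_r + t_l)) * 100
  )
  if (pseudo) attr(out, "pseudo_sides") <- TRUE
  out
}

#' Per-step descriptive statistics
#'
#' The 27 descriptive features over a window's frames: minimum, maximum
#' and mean of the ML, AP and vertical linear accelerations; mean and
#' range of tilt, rotation and obliquity; sample standard deviation and
#' RMS (\eqn{\sqrt{\mathrm{mean}(x^2)}}) of all six channels.
#'
#' @param rec A uniform [imu_recording()].
#' @param w A single-row `step_windows` entry (or a list with
#'   `start_frame` / `end_frame`).
#' @return Named numeric vector of 27 values in registry order.
#' @export
window_stats <- function(rec, w) {
  if (w$end_frame <= w$start_frame) stop("empty step window")
  idx <- w$start_frame:(w$end_frame - 1L)
  chans <- feature_channels()
  x <- lapply(chans, function(ch) rec[[ch]][idx])
  acc <- c("ml", "ap", "vert")
  ang <- c("tilt", "rotation", "obliquity")
  c(
    setNames(vapply(x[acc], min, 0), paste0("min_", acc)),
    setNames(vapply(x[acc], max, 0), paste0("max_", acc)),
    setNames(vapply(x[acc], mean, 0), paste0("mean_", acc)),
    setNames(vapply(x[ang], mean, 0), paste0("mean_", ang)),
    setNames(vapply(x[ang], function(v) diff(range(v)), 0),
             paste0("range_", ang)),
    setNames(vapply(x, sd, 0), paste0("sd_", names(chans))),
    setNames(vapply(x, function(v) sqrt(mean(v^2)), 0),
             paste0("rms_", names(chans)))
  )
}

# single-sided magnitude spectrum of a mean-removed, zero-padded window
magnitude_spectrum <- function(x, n_fft) {
  n_fft <- max(n_fft, length(x))
  xx <- c(x - mean(x), rep(0, n_fft - length(x)))
  Mod(fft(xx))[seq_len(n_fft %/% 2 + 1L)]
}

#' Per-step spectral features
#'
#' For each of the six channels, from the single-sided magnitude
#' spectrum of the mean-removed window (zero-padded to `n_fft`):
#' the 25th percentile of magnitudes (quartile FFT), the largest
#' magnitude (maximum FFT), the standard deviation of magnitudes
#' (SD FFT), the peak distinction \eqn{(\max - \mathrm{mean}) / \max}
#' (0 for a flat spectrum), and REOH, the ratio of even-harmonic power
#' to total harmonic power at integer multiples of the step frequency
#' up to Nyquist, each harmonic read from its nearest spectral bin.
#'
#' @param rec A uniform [imu_recording()].
#' @param w A single-row `step_windows` entry (at least 4 frames).
#' @param step_freq Step frequency in Hz (> 0).
#' @param n_fft Zero-padding length (default 256).
#' @return Named numeric vector of 30 values in registry order.
#' @export
spectral_features <- function(rec, w, step_freq, n_fft = 256L) {
  if (step_freq <= 0) stop("step_freq must be positive")
  if (w$end_frame - w$start_frame < 4L) {
    stop("spectral features need a window of >= 4 frames")
  }
  idx <- w$start_frame:(w$end_frame - 1L)
  fs <- sample_rate(rec)
  chans <- feature_channels()
  per_chan <- vapply(chans, function(ch) {
    mag <- magnitude_spectrum(rec[[ch]][idx], n_fft)
    nf <- 2L * (length(mag) - 1L)
    m_max <- max(mag)
    pd <- if (m_max > 0) (m_max - mean(mag)) / m_max else 0
    harmonics <- seq_len(floor((fs / 2) / step_freq))
    even_p <- 0; odd_p <- 0
    for (h in harmonics) {
      bin <- round(h * step_freq * nf / fs) + 1L
      bin <- min(bin, length(mag))
      p <- mag[bin]^2
      if (h %% 2 == 0) even_p <- even_p + p else odd_p <- odd_p + p
    }
    reoh <- if (even_p + odd_p > 0) even_p / (even_p + odd_p) else 0
    c(quartile = unname(quantile(mag, 0.25)), max = m_max,
      sd = sd(mag), pd = pd, reoh = reoh)
  }, numeric(5))
  ch <- names(chans)
  c(setNames(per_chan["quartile", ], paste0("fft_quartile_", ch)),
    setNames(per_chan["max", ], paste0("fft_max_", ch)),
    setNames(per_chan["sd", ], paste0("fft_sd_", ch)),
    setNames(per_chan["pd", ], paste0("fft_peak_distinction_", ch)),
    setNames(per_chan["reoh", ], paste0("reoh_", ch)))
}

#' Compute the full step-feature table
#'
#' Segments the walk, computes the 62 registry features for every
#' included step (temporal features use physical neighbours, so turn
#' exclusion happens after temporal attribution), and returns one row
#' per step. The step frequency driving the harmonic analysis is the
#' reciprocal of the median included step time.
#'
#' @param rec A filtered, uniform [imu_recording()].
#' @param events [foot_strike_events()] (>= 3 events).
#' @param exclude_turns Drop turn windows (default `TRUE`).
#' @param turn_threshold Rotation-rate threshold in degrees/s.
#' @param n_fft Spectral zero-padding length.
#' @return A `step_feature_table`: `step`, `start_frame`, `end_frame`,
#'   `side`, then the 62 columns of [feature_registry()].
#' @export
step_features <- function(rec, events, exclude_turns = TRUE,
                          turn_threshold = 45, n_fft = 256L) {
  all_w <- segment_steps(events, rec, exclude_turns = FALSE,
                         turn_threshold = turn_threshold)
  tf <- suppressWarnings(temporal_features(all_w))
  keep <- if (exclude_turns) !all_w$in_turn else rep(TRUE, nrow(all_w))
  keep <- keep & (all_w$end_frame - all_w$start_frame >= 4L)
  if (!any(keep)) stop("no step windows left after exclusion")
  step_freq <- 1 / median(all_w$duration[keep])
  rows <- lapply(which(keep), function(i) {
    w <- all_w[i, ]
    c(tf[i, ], window_stats(rec, w),
      spectral_features(rec, w, step_freq, n_fft))
  })
  m <- do.call(rbind, rows)
  stopifnot(identical(colnames(m), feature_registry()))
  out <- data.frame(step = which(keep),
                    start_frame = all_w$start_frame[keep],
                    end_frame = all_w$end_frame[keep],
                    side = all_w$side[keep],
                    m, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, step_freq = step_freq,
            class = c("step_feature_table", "data.frame"))
}

#' Aggregate steps to a participant vector
#'
#' Minimum, maximum, mean and sample standard deviation of each of the
#' 62 step features over all included steps: 248 values in
#' feature-major order (`f1_min, f1_max, f1_mean, f1_sd, f2_min, ...`).
#'
#' @param table A `step_feature_table` with at least 2 rows.
#' @param fall_risk Logical fall-risk label.
#' @param participant_id Identifier string.
#' @return A `participant_vector`: list with `features` (named numeric,
#'   length 248), `fall_risk`, `participant_id`.
#' @export
aggregate_participant <- function(table, fall_risk = NA,
                                  participant_id = "P") {
  if (nrow(table) < 2) {
    stop("aggregation needs at least 2 steps (sample SD undefined)")
  }
  feats <- vapply(feature_registry(), function(f) {
    v <- table[[f]]
    c(min = min(v), max = max(v), mean = mean(v), sd = sd(v))
  }, numeric(4))
  vec <- setNames(as.vector(feats),
                  as.vector(outer(c("min", "max", "mean", "sd"),
                                  feature_registry(),
                                  function(s, f) paste(f, s, sep = "_"))))
  stopifnot(identical(names(vec), participant_registry()))
  structure(list(features = vec, fall_risk = fall_risk,
                 participant_id = participant_id),
            class = "participant_vector")
}

#' @export
print.participant_vector <- function(x, ...) {
  cat(sprintf("<participant_vector> %s: %d features, fall risk = %s\n",
              x$participant_id, length(x$features), x$fall_risk))
  invisible(x)
}

#' Bind participant vectors into a cohort table
#'
#' @param vectors List of [aggregate_participant()] results.
#' @return Data frame: `participant_id`, `fall_risk`, then the 248
#'   feature columns in registry order.
#' @export
bind_participants <- function(vectors) {
  stopifnot(length(vectors) > 0)
  feats <- do.call(rbind, lapply(vectors, function(v) v$features))
  out <- data.frame(
    participant_id = vapply(vectors, function(v) v$participant_id, ""),
    fall_risk = vapply(vectors, function(v) isTRUE(v$fall_risk),
                       logical(1)),
    feats, check.names = FALSE
  )
  rownames(out) <- NULL
  out
}
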