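# Synthetic 6MWT gait generator: quasi-periodic step pulses with known
# ground-truth foot strikes, hallway turns, and fall-risk-linked cohorts.

#' Gait simulation parameters
#'
#' Conditions of a simulated six-minute walk test: a subject walking a
#' 20 m hallway at 50 Hz sampling, turning 180 degrees at each end.
#' Each foot strike produces an anterior-posterior (AP) acceleration
#' pulse followed 0.06 s later by a vertical pulse; medio-lateral sway
#' oscillates at the stride frequency; white sensor noise is added to
#' every signal channel.
#'
#' @param duration Trial length in s (default 360, a full 6MWT).
#' @param sample_rate Sampling rate in Hz (default 50).
#' @param cadence Steps per minute (default 110).
#' @param step_time_asymmetry Right/left step-time ratio (default 1,
#'   symmetric gait; amputee gait is typically > 1).
#' @param ap_peak_amp,vert_peak_amp,ml_amp Pulse and sway amplitudes in
#'   m/s^2 (defaults 2.5, 3, 1).
#' @param noise_sd Additive white-noise standard deviation in m/s^2
#'   (default 0.15).
#' @param walk_speed Walking speed in m/s (default 1), setting the time
#'   between turns together with `hallway_length`.
#' @param hallway_length Hallway length in m (default 20).
#' @param turn_duration Duration of each 180-degree turn in s (default 2).
#' @param seed Integer seed; identical seeds give bit-identical walks.
#' @return A `gait_sim_params` list.
#' @export
gait_sim_params <- function(duration = 360, sample_rate = 50,
                            cadence = 110, step_time_asymmetry = 1,
                            ap_peak_amp = 2.5, vert_peak_amp = 3,
                            ml_amp = 1, noise_sd = 0.15,
                            walk_speed = 1, hallway_length = 20,
                            turn_duration = 2, seed = 1L) {
  p <- list(duration = duration, sample_rate = sample_rate,
            cadence = cadence, step_time_asymmetry = step_time_asymmetry,
            ap_peak_amp = ap_peak_amp, vert_peak_amp = vert_peak_amp,
            ml_amp = ml_amp, noise_sd = noise_sd, walk_speed = walk_speed,
            hallway_length = hallway_length,
            turn_duration = turn_duration, seed = as.integer(seed))
  if (p$cadence <= 0) stop("cadence must be positive")
  if (p$step_time_asymmetry <= 0) stop("asymmetry ratio must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (p$hallway_length <= 0) stop("hallway_length must be positive")
  if (p$duration <= 0 || p$sample_rate <= 0) {
    stop("duration and sample_rate must be positive")
  }
  structure(p, class = "gait_sim_params")
}

# unit-height Gaussian pulse added in place around each centre frame
add_pulses <- function(y, centres_s, amps, t, sigma = 0.05) {
  fs <- 1 / (t[2] - t[1])
  half <- ceiling(4 * sigma * fs)
  n <- length(y)
  for (i in seq_along(centres_s)) {
    c_f <- round(centres_s[i] * fs) + 1L
    lo <- max(1L, c_f - half)
    hi <- min(n, c_f + half)
    if (lo > hi) next
    y[lo:hi] <- y[lo:hi] +
      amps[i] * exp(-((t[lo:hi] - centres_s[i])^2) / (2 * sigma^2))
  }
  y
}

#' Generate a synthetic walk with ground-truth foot strikes
#'
#' Builds an [imu_recording()] at the uniform sample rate together with
#' the exact foot-strike events that produced it. Strikes alternate
#' sides (left first); the interval ending in a right strike is the
#' right step time, so the right/left step-time ratio equals
#' `step_time_asymmetry`. Strike times are snapped to the sampling grid
#' so the truth event frames are exact. During turns the step pulses
#' are attenuated to half amplitude, the rotation angle ramps through
#' 180 degrees, and the vertical-axis angular velocity is elevated.
#'
#' @param params A [gait_sim_params()] object.
#' @return List with elements `recording` (`imu_recording`), `events`
#'   (`foot_strike_events` ground truth) and `params`.
#' @export
generate_walk <- function(params = gait_sim_params()) {
  stopifnot(inherits(params, "gait_sim_params"))
  p <- params
  set.seed(p$seed)
  fs <- p$sample_rate
  n <- round(p$duration * fs)
  t <- (seq_len(n) - 1L) / fs

  # alternating step schedule: left strike first, then right after the
  # right step time, etc.; mean step time from cadence, split by the
  # right/left ratio r: tL = 2T/(1+r), tR = r*tL
  T_step <- 60 / p$cadence
  t_left <- 2 * T_step / (1 + p$step_time_asymmetry)
  t_right <- p$step_time_asymmetry * t_left
  strikes <- numeric(0)
  sides <- character(0)
  tt <- 0.5        # first strike half a second in
  side <- "left"
  while (tt < p$duration - 0.25) {
    strikes <- c(strikes, tt)
    sides <- c(sides, side)
    tt <- tt + if (side == "left") t_right else t_left
    side <- if (side == "left") "right" else "left"
  }
  frames <- round(strikes * fs) + 1L
  strikes <- (frames - 1L) / fs          # snap to the sampling grid

  # turn schedule: a 180-degree turn every hallway traversal
  lap <- p$hallway_length / p$walk_speed
  turn_starts <- if (lap + p$turn_duration >= p$duration) {
    numeric(0)
  } else {
    seq(lap, p$duration - p$turn_duration, by = lap)
  }
  in_turn <- rep(FALSE, n)
  rot <- rep(0, n)
  gz <- rnorm(n, 0, 0.02)
  heading <- 0
  for (ts in turn_starts) {
    idx <- which(t >= ts & t < ts + p$turn_duration)
    if (length(idx) == 0) next
    in_turn[idx] <- TRUE
    ramp <- (t[idx] - ts) / p$turn_duration
    dirn <- if (heading == 0) 1 else -1
    rot[idx] <- heading + dirn * 180 * ramp
    heading <- heading + dirn * 180
    rot[t >= ts + p$turn_duration] <- heading
    gz[idx] <- gz[idx] + dirn * pi / p$turn_duration
  }
  strike_in_turn <- in_turn[frames]
  amp_fac <- ifelse(strike_in_turn, 0.5, 1)

  lin_ap <- add_pulses(rep(0, n), strikes, p$ap_peak_amp * amp_fac, t)
  lin_vert <- add_pulses(rep(0, n), strikes + 0.06,
                         p$vert_peak_amp * amp_fac, t)
  # ML sway at the stride frequency, leftward (negative) at left strikes
  f_stride <- 1 / (t_left + t_right)
  lin_ml <- -p$ml_amp * cos(2 * pi * f_stride * (t - strikes[1]))

  f_step <- 1 / T_step
  tilt <- 5 + 2 * sin(2 * pi * f_step * (t - strikes[1]))
  obli <- 1.5 * sin(2 * pi * f_stride * (t - strikes[1]))

  nz <- function(s = p$noise_sd) rnorm(n, 0, s)
  rec <- data.frame(
    time_s = t,
    ax = lin_ml + nz(), ay = 9.81 + lin_vert + nz(), az = lin_ap + nz(),
    lin_ap = lin_ap + nz(), lin_ml = lin_ml + nz(),
    lin_vert = lin_vert + nz(),
    gx = nz(p$noise_sd * 0.1), gy = nz(p$noise_sd * 0.1),
    gz = gz + nz(p$noise_sd * 0.1),
    tilt_deg = tilt + nz(p$noise_sd * 0.5),
    obliquity_deg = obli + nz(p$noise_sd * 0.5),
    rotation_deg = rot + nz(p$noise_sd * 0.5)
  )
  list(recording = imu_recording(rec, sample_rate = fs),
       events = foot_strike_events(frames, strikes, sides),
       params = p)
}

#' Cohort specification
#'
#' Class-conditional parameter distributions for a simulated cohort.
#' Defaults emulate a fall-risk group walking slower, more
#' asymmetrically and with noisier signals than the no-fall-risk group,
#' at the 27 / 53 class split of an 80-participant amputee cohort.
#'
#' @param n_fall_risk,n_no_fall_risk Class sizes (defaults 27 and 53).
#' @param fall_risk,no_fall_risk Named lists with `mean` / `sd` pairs
#'   for `cadence`, `asymmetry` and `noise_sd`.
#' @param duration Walk duration in s passed to every member.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_fall_risk = 27, n_no_fall_risk = 53,
                        fall_risk = list(
                          cadence = c(mean = 88, sd = 8),
                          asymmetry = c(mean = 1.18, sd = 0.06),
                          noise_sd = c(mean = 0.25, sd = 0.05)),
                        no_fall_risk = list(
                          cadence = c(mean = 106, sd = 8),
                          asymmetry = c(mean = 1.05, sd = 0.03),
                          noise_sd = c(mean = 0.15, sd = 0.03)),
                        duration = 360, seed = 1L) {
  if (n_fall_risk < 0 || n_no_fall_risk < 0) stop("counts must be >= 0")
  for (cl in list(fall_risk, no_fall_risk)) {
    if (any(vapply(cl, function(x) x[["sd"]], 0) < 0)) {
      stop("distribution sds must be >= 0")
    }
  }
  structure(list(n_fall_risk = n_fall_risk,
                 n_no_fall_risk = n_no_fall_risk,
                 fall_risk = fall_risk, no_fall_risk = no_fall_risk,
                 duration = duration, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of labelled synthetic walks
#'
#' Draws per-member gait parameters from the class-conditional
#' distributions of a [cohort_spec()] (truncated to valid ranges) and
#' simulates each walk.
#'
#' @param spec A [cohort_spec()].
#' @return List of members, each a list with `recording`, `events`,
#'   `fall_risk` (logical label), `participant_id` and `params`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  labels <- c(rep(TRUE, spec$n_fall_risk), rep(FALSE, spec$n_no_fall_risk))
  draws <- lapply(seq_along(labels), function(i) {
    cl <- if (labels[i]) spec$fall_risk else spec$no_fall_risk
    list(
      cadence = max(40, rnorm(1, cl$cadence[["mean"]], cl$cadence[["sd"]])),
      asymmetry = max(0.5, rnorm(1, cl$asymmetry[["mean"]],
                                 cl$asymmetry[["sd"]])),
      noise_sd = max(0, rnorm(1, cl$noise_sd[["mean"]],
                              cl$noise_sd[["sd"]])),
      seed = sample.int(.Machine$integer.max, 1)
    )
  })
  lapply(seq_along(labels), function(i) {
    d <- draws[[i]]
    w <- generate_walk(gait_sim_params(
      duration = spec$duration, cadence = d$cadence,
      step_time_asymmetry = d$asymmetry, noise_sd = d$noise_sd,
      seed = d$seed))
    c(w, list(fall_risk = labels[i],
              participant_id = sprintf("P%03d", i)))
  })
}

#' Degrade frame labels
#'
#' Stress input for the post-processing corrections: drops each truth
#' strike independently, jitters the survivors, and appends duplicate
#' predictions at adjacent frames.
#'
#' @param truth A [frame_labels()] binary vector.
#' @param drop_rate,duplicate_rate Probabilities in `[0, 1]`.
#' @param jitter_frames Maximum uniform jitter (frames).
#' @param seed Integer seed.
#' @return Degraded `frame_labels` of the same length.
#' @export
degrade_labels <- function(truth, drop_rate = 0, duplicate_rate = 0,
                           jitter_frames = 0L, seed = 1L) {
  if (drop_rate < 0 || drop_rate > 1 || duplicate_rate < 0 ||
      duplicate_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  n <- length(truth)
  strikes <- which(truth == 1L)
  keep <- strikes[runif(length(strikes)) >= drop_rate]
  if (jitter_frames > 0 && length(keep) > 0) {
    keep <- keep + sample(seq.int(-jitter_frames, jitter_frames),
                          length(keep), replace = TRUE)
  }
  dup <- keep[runif(length(keep)) < duplicate_rate]
  if (length(dup) > 0) {
    dup <- dup + sample(c(-1L, 1L), length(dup), replace = TRUE)
  }
  out <- rep(0L, n)
  idx <- c(keep, dup)
  idx <- idx[idx >= 1L & idx <= n]
  out[idx] <- 1L
  frame_labels(out)
}
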