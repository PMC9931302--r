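# Foot-strike containers, rule-based labelling, and the post-processing
# corrections: duplicate collapse, adaptive locking period, missed-step
# insertion, side assignment, and frame-wise detection metrics.

#' Per-frame foot-strike labels
#'
#' @param labels Integer/numeric vector of 0 (no foot strike present)
#'   and 1 (foot strike present), one per frame.
#' @return A `frame_labels` integer vector.
#' @export
frame_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(labels, class = "frame_labels")
}

#' @export
print.frame_labels <- function(x, ...) {
  cat(sprintf("<frame_labels> %d frames, %d strike(s)\n",
              length(x), sum(x)))
  invisible(x)
}

#' Foot-strike event list
#'
#' @param frame 1-based frame indices, strictly increasing.
#' @param time_s Event times in seconds.
#' @param side `"left"`, `"right"` or `"unknown"`; adjacent assigned
#'   sides must alternate.
#' @return A `foot_strike_events` data frame (`frame`, `time_s`, `side`).
#' @export
foot_strike_events <- function(frame = integer(0),
                               time_s = numeric(0),
                               side = rep("unknown", length(frame))) {
  frame <- as.integer(frame)
  if (length(frame) > 1 && any(diff(frame) <= 0)) {
    stop("event frames must be strictly increasing")
  }
  side <- as.character(side)
  if (!all(side %in% c("left", "right", "unknown"))) {
    stop("side must be left, right or unknown")
  }
  assigned <- side != "unknown"
  if (sum(assigned) > 1) {
    adj <- which(assigned[-length(side)] & assigned[-1])
    if (any(side[adj] == side[adj + 1L])) {
      stop("adjacent assigned sides must alternate")
    }
  }
  structure(data.frame(frame = frame, time_s = as.numeric(time_s),
                       side = side, stringsAsFactors = FALSE),
            class = c("foot_strike_events", "data.frame"))
}

#' @export
print.foot_strike_events <- function(x, ...) {
  cat(sprintf("<foot_strike_events> %d event(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Convert events to per-frame labels
#' @param events A [foot_strike_events()] object.
#' @param n_frames Recording length in frames.
#' @return [frame_labels()] of length `n_frames`.
#' @export
events_to_labels <- function(events, n_frames) {
  out <- rep(0L, n_frames)
  out[events$frame[events$frame >= 1 & events$frame <= n_frames]] <- 1L
  frame_labels(out)
}

# local maxima above a threshold; strictly above both neighbours on at
# least one side, not below on the other
local_maxima <- function(x, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  idx <- i[(x[i] > x[i - 1] & x[i] >= x[i + 1]) |
             (x[i] >= x[i - 1] & x[i] > x[i + 1])]
  idx[x[idx] >= min_height]
}

#' Rule-based foot-strike labelling
#'
#' Reference labeller implementing the ground-truth identification rule:
#' a foot strike is an anterior-posterior (AP) acceleration peak
#' immediately followed by a vertical acceleration peak. AP local maxima
#' above `min_height_frac` of the trial maximum, separated by at least
#' the adaptive locking period, become events when a vertical local
#' maximum follows within `vert_window` seconds.
#'
#' @param rec A filtered, uniform [imu_recording()] with `lin_ap` and
#'   `lin_vert` channels.
#' @param vert_window Pairing window in s (default 0.1).
#' @param min_height_frac AP peak threshold as a fraction of the trial
#'   maximum (default 0.2).
#' @param lock Locking period in frames; computed with
#'   [compute_locking_period()] when `NULL`.
#' @return [foot_strike_events()] with sides unassigned.
#' @export
label_rule_based <- function(rec, vert_window = 0.1,
                             min_height_frac = 0.2, lock = NULL) {
  fs <- sample_rate(rec)
  if (is.null(fs)) stop("recording must be resampled to a uniform rate")
  ap <- rec$lin_ap
  vert <- rec$lin_vert
  if (is.null(ap) || is.null(vert)) {
    stop("recording needs lin_ap and lin_vert channels")
  }
  if (is.null(lock)) {
    lock <- tryCatch(compute_locking_period(rec),
                     error = function(e) 10L)
  }
  if (max(ap) <= 0) return(foot_strike_events())
  ap_peaks <- local_maxima(ap, min_height = min_height_frac * max(ap))
  # enforce the locking period, keeping the taller of two close peaks
  if (length(ap_peaks) > 1) {
    keep <- ap_peaks[order(-ap[ap_peaks], ap_peaks)]
    sel <- integer(0)
    for (p in keep) {
      if (all(abs(sel - p) >= lock)) sel <- c(sel, p)
    }
    ap_peaks <- sort(sel)
  }
  vert_peaks <- local_maxima(vert, min_height = min_height_frac *
                               max(vert, 0))
  win <- round(vert_window * fs)
  hit <- vapply(ap_peaks, function(p) {
    any(vert_peaks > p & vert_peaks <= p + win)
  }, logical(1))
  ev <- ap_peaks[hit]
  foot_strike_events(ev, rec$time_s[ev])
}

#' Adaptive locking period
#'
#' Refractory interval after a detected step, derived from the first
#' 5 s of the filtered vertical acceleration: the dominant step period
#' is the smallest autocorrelation-peak lag (autocorrelation above 0.2,
#' lag at least 0.24 s) and the locking period is half that period,
#' clamped to `clamp` frames. White noise, which has no qualifying
#' autocorrelation peak, returns the lower clamp bound.
#'
#' @param rec A filtered, uniform [imu_recording()] at least 5 s long.
#' @param clamp Length-2 integer clamp bounds in frames (default
#'   `c(10, 35)`).
#' @param window_s Length of the initial sample in s (default 5).
#' @return Locking period in frames (integer).
#' @export
compute_locking_period <- function(rec, clamp = c(10L, 35L),
                                   window_s = 5) {
  fs <- sample_rate(rec)
  if (is.null(fs)) stop("recording must be resampled to a uniform rate")
  n_win <- round(window_s * fs)
  if (nrow(rec) < n_win) {
    stop("recording shorter than the ", window_s, " s locking window")
  }
  v <- rec$lin_vert[seq_len(n_win)]
  lag_max <- min(n_win - 2L, round(2 * fs))
  a <- as.numeric(acf(v, lag.max = lag_max, plot = FALSE,
                      demean = TRUE)$acf)[-1]
  peaks <- local_maxima(a, min_height = 0.2)
  peaks <- peaks[peaks >= round(0.24 * fs)]
  if (length(peaks) == 0) return(as.integer(clamp[1]))
  period <- peaks[1]
  as.integer(min(max(floor(0.5 * period), clamp[1]), clamp[2]))
}

#' Collapse runs of consecutive foot-strike predictions
#'
#' Each maximal run of consecutive 1-labels becomes a single event at
#' the frame of peak AP acceleration within the run (earliest frame on
#' ties); isolated 1-labels pass through.
#'
#' @param labels [frame_labels()].
#' @param ap AP acceleration, same length as `labels`.
#' @param time_s Frame times in s; defaults to a 50 Hz grid from 0.
#' @return [foot_strike_events()] with sides unassigned.
#' @export
collapse_duplicates <- function(labels, ap,
                                time_s = (seq_along(ap) - 1) / 50) {
  if (length(labels) != length(ap)) {
    stop("labels and ap must have the same length")
  }
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  one <- which(r$values == 1L)
  frames <- vapply(one, function(i) {
    run <- starts[i]:ends[i]
    run[which.max(ap[run])]
  }, integer(1))
  foot_strike_events(frames, time_s[frames])
}

#' Insert missed foot strikes
#'
#' Scans inter-event gaps longer than `gap_factor` times the preceding
#' step duration (the interval between the two events before the gap;
#' the first gap uses the trial-median interval). Each qualifying gap is
#' shrunk by half the locking period at both ends and a strike is
#' inserted at the AP local maximum within the shrunken range, provided
#' it stays at least `lock` frames from both neighbours; the scan
#' repeats until no qualifying gap can be filled.
#'
#' @param events Sorted [foot_strike_events()].
#' @param ap AP acceleration covering all event frames.
#' @param lock Locking period in frames.
#' @param gap_factor Gap threshold multiplier (default 1.5).
#' @param time_s Frame times; defaults to a 50 Hz grid from 0.
#' @return [foot_strike_events()] including the original events.
#' @export
insert_missed <- function(events, ap, lock, gap_factor = 1.5,
                          time_s = (seq_along(ap) - 1) / 50) {
  if (nrow(events) < 3) return(events)
  frames <- events$frame
  sides <- events$side
  half <- ceiling(lock / 2)
  repeat {
    inserted <- FALSE
    d <- diff(frames)
    med <- median(d)
    for (i in seq_along(d)) {
      prev <- if (i >= 2) d[i - 1] else med
      if (d[i] <= gap_factor * prev) next
      lo <- frames[i] + half
      hi <- frames[i + 1] - half
      if (lo > hi) next
      cand <- local_maxima(ap)
      cand <- cand[cand >= lo & cand <= hi &
                     cand - frames[i] >= lock &
                     frames[i + 1] - cand >= lock]
      if (length(cand) == 0) next
      new_f <- cand[which.max(ap[cand])]
      frames <- append(frames, new_f, after = i)
      sides <- append(sides, "unknown", after = i)
      inserted <- TRUE
      break
    }
    if (!inserted) break
  }
  foot_strike_events(frames, time_s[frames], sides)
}

# alternate sides starting from the ML-sway sign at the first strike
assign_sides <- function(events, ml, flat_eps = 1e-6) {
  n <- nrow(events)
  if (n == 0) return(events)
  m1 <- ml[events$frame[1]]
  if (is.null(ml) || is.na(m1) || abs(m1) < flat_eps) return(events)
  first <- if (m1 < 0) "left" else "right"
  sides <- rep(c(first, setdiff(c("left", "right"), first)),
               length.out = n)
  foot_strike_events(events$frame, events$time_s, sides)
}

#' Post-process predicted foot-strike labels
#'
#' The correction pipeline for model prediction errors: collapse runs of
#' consecutive predictions to the AP peak, enforce the adaptive locking
#' period (of two events closer than the locking period the one with
#' the larger AP value is kept), insert missed steps in over-long gaps,
#' and assign alternating sides from the medio-lateral sway sign at the
#' first strike (all `unknown` when the ML signal is flat or absent).
#'
#' @param labels [frame_labels()] aligned with `rec`.
#' @param rec A filtered, uniform [imu_recording()].
#' @param gap_factor Gap threshold multiplier (default 1.5).
#' @param lock Locking period in frames; computed from `rec` when
#'   `NULL`.
#' @return Final cleaned [foot_strike_events()].
#' @export
postprocess <- function(labels, rec, gap_factor = 1.5, lock = NULL) {
  if (length(labels) != nrow(rec)) {
    stop("labels must align with the recording")
  }
  ap <- rec$lin_ap
  ev <- collapse_duplicates(labels, ap, rec$time_s)
  if (nrow(ev) == 0) return(ev)
  if (is.null(lock)) {
    lock <- tryCatch(compute_locking_period(rec),
                     error = function(e) 10L)
  }
  # locking-period enforcement: drop the weaker of two close events
  frames <- ev$frame
  while (length(frames) > 1 && any(diff(frames) < lock)) {
    i <- which(diff(frames) < lock)[1]
    drop <- if (ap[frames[i]] >= ap[frames[i + 1]]) i + 1L else i
    frames <- frames[-drop]
  }
  ev <- foot_strike_events(frames, rec$time_s[frames])
  ev <- insert_missed(ev, ap, lock, gap_factor, rec$time_s)
  assign_sides(ev, rec$lin_ml)
}

# dilate a binary vector by +/- tol frames
dilate_labels <- function(x, tol) {
  if (tol <= 0) return(as.integer(x != 0))
  idx <- which(x != 0)
  out <- rep(0L, length(x))
  if (length(idx) > 0) {
    hits <- unique(as.vector(outer(idx, -tol:tol, `+`)))
    hits <- hits[hits >= 1 & hits <= length(x)]
    out[hits] <- 1L
  }
  out
}

#' Frame-wise detection metrics
#'
#' Accuracy, sensitivity and specificity of predicted versus truth
#' frame labels. With `tolerance_frames > 0`, a predicted strike within
#' that many frames of a truth strike counts as correct (and a truth
#' strike with a prediction within the window counts as detected).
#'
#' @param pred,truth [frame_labels()] of equal length.
#' @param tolerance_frames Matching tolerance in frames (default 0,
#'   strict frame-wise agreement).
#' @return List with `accuracy`, `sensitivity`, `specificity`
#'   (proportions; `NA` where a margin is empty).
#' @export
detection_metrics <- function(pred, truth, tolerance_frames = 0L) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length")
  }
  n <- length(truth)
  tol <- as.integer(tolerance_frames)
  fp <- sum(pred == 1L & dilate_labels(truth, tol) == 0L)
  fn <- sum(truth == 1L & dilate_labels(pred, tol) == 0L)
  n_pos <- sum(truth == 1L)
  n_neg <- n - n_pos
  list(
    accuracy = (n - fp - fn) / n,
    sensitivity = if (n_pos == 0) NA_real_ else 1 - fn / n_pos,
    specificity = if (n_neg == 0) NA_real_ else 1 - fp / n_neg
  )
}

#' Match events against ground truth
#'
#' Greedy one-to-one matching of predicted to truth events within a
#' frame tolerance; the basis for event-level recovery rates.
#'
#' @param pred,truth [foot_strike_events()].
#' @param tolerance_frames Maximum frame distance for a match.
#' @return List with `n_matched`, `recall` (matched / truth events) and
#'   `precision` (matched / predicted events).
#' @export
match_events <- function(pred, truth, tolerance_frames = 2L) {
  pf <- pred$frame
  used <- rep(FALSE, length(pf))
  matched <- 0L
  for (f in truth$frame) {
    d <- abs(pf - f)
    d[used] <- Inf
    if (length(d) > 0 && min(d) <= tolerance_frames) {
      used[which.min(d)] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_matched = matched,
       recall = if (nrow(truth) == 0) NA_real_ else matched / nrow(truth),
       precision = if (nrow(pred) == 0) NA_real_
                   else matched / nrow(pred))
}
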