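# Canonical channel and feature registries. Column order is part of the
# on-disk contract: CSV headers, feature tables and participant vectors
# all follow these vectors verbatim.

#' Recording CSV column registry
#'
#' Canonical column names of the recording CSV dialect, in order:
#' timestamps, raw device-frame acceleration, body-frame linear
#' acceleration (gravity removed; AP positive forward, ML positive
#' rightward, vertical positive upward), angular velocity, and pelvis
#' orientation angles (tilt about ML, obliquity about AP, rotation about
#' the vertical axis).
#'
#' @return Character vector of the 13 column names.
#' @export
recording_channels <- function() {
  c("time_s", "ax", "ay", "az",
    "lin_ap", "lin_ml", "lin_vert",
    "gx", "gy", "gz",
    "tilt_deg", "obliquity_deg", "rotation_deg")
}

# signal channels (everything except the time base)
signal_channels <- function() setdiff(recording_channels(), "time_s")

# the six channels feeding descriptive + spectral step features
feature_channels <- function() {
  c(ml = "lin_ml", ap = "lin_ap", vert = "lin_vert",
    tilt = "tilt_deg", rotation = "rotation_deg",
    obliquity = "obliquity_deg")
}

#' Step-feature registry
#'
#' Fixed, ordered names of the 62 per-step features: 5 temporal
#' (cadence, right/left step time, stride time, symmetry index), 27
#' descriptive statistics over the step window, and 30 spectral
#' descriptors (quartile, maximum, standard deviation and peak
#' distinction of the FFT magnitude spectrum, and the ratio of
#' even-to-odd harmonic power, for each of the six signal channels).
#'
#' @return Character vector of length 62; aggregation order for the
#'   248-entry participant vector is feature-major
#'   (`<feature>_min`, `_max`, `_mean`, `_sd`).
#' @export
feature_registry <- function() {
  ch <- names(feature_channels())
  c(
    "cadence", "step_time_right", "step_time_left", "stride_time",
    "symmetry_index",
    paste0("min_", c("ml", "ap", "vert")),
    paste0("max_", c("ml", "ap", "vert")),
    paste0("mean_", c("ml", "ap", "vert")),
    paste0("mean_", c("tilt", "rotation", "obliquity")),
    paste0("range_", c("tilt", "rotation", "obliquity")),
    paste0("sd_", ch),
    paste0("rms_", ch),
    paste0("fft_quartile_", ch),
    paste0("fft_max_", ch),
    paste0("fft_sd_", ch),
    paste0("fft_peak_distinction_", ch),
    paste0("reoh_", ch)
  )
}

#' Participant-vector registry
#'
#' Ordered names of the 248 aggregated features: for each entry of
#' [feature_registry()], its minimum, maximum, mean and sample standard
#' deviation across all included steps.
#'
#' @return Character vector of length 248.
#' @export
participant_registry <- function() {
  as.vector(t(outer(feature_registry(), c("min", "max", "mean", "sd"),
                    paste, sep = "_")))
}
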