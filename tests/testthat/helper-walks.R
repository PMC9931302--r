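# Shared fixtures: short synthetic walks, preprocessed once per file.

make_walk <- function(duration = 60, noise_sd = 0.15, seed = 7, ...) {
  w <- generate_walk(gait_sim_params(duration = duration,
                                     noise_sd = noise_sd, seed = seed,
                                     ...))
  w$prec <- preprocess_recording(w$recording)
  w$truth_labels <- events_to_labels(w$events, nrow(w$prec))
  w
}

# labelled walks with varied gait for detector training; deterministic
make_detector_walks <- function(n, duration = 60, seed = 100) {
  set.seed(seed)
  cad <- runif(n, 90, 115)
  asym <- runif(n, 1, 1.2)
  seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    w <- make_walk(duration = duration, noise_sd = 0.15,
                   seed = seeds[i], cadence = cad[i],
                   step_time_asymmetry = asym[i])
    list(recording = w$prec, labels = w$truth_labels,
         events = w$events)
  })
}

# minimal uniform recording around a single channel
make_channel_rec <- function(x, channel = "lin_vert", rate = 50) {
  df <- data.frame(time_s = (seq_along(x) - 1) / rate)
  df[[channel]] <- x
  imu_recording(df, sample_rate = rate)
}
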