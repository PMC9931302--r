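# Trainable per-frame foot-strike sequence labeller: a class-weighted
# random forest over a sliding window of sensor context around each
# frame (orientation, raw and linear acceleration, angular velocity).

#' Detector configuration
#'
#' @param window_frames Half-width of the context window in frames; the
#'   model sees `2 * window_frames + 1` frames per channel (default 5,
#'   i.e. 0.2 s of context at 50 Hz).
#' @param channels Input channels; defaults to every signal channel.
#' @param num_trees Forest size (default 100).
#' @param threshold Posterior probability above which a frame is
#'   labelled a strike (default 0.5).
#' @return A `detector_config` list.
#' @export
detector_config <- function(window_frames = 5L,
                            channels = signal_channels(),
                            num_trees = 100L, threshold = 0.5) {
  structure(list(window_frames = as.integer(window_frames),
                 channels = channels,
                 num_trees = as.integer(num_trees),
                 threshold = threshold,
                 version = 1L),
            class = "detector_config")
}

# sliding-window design matrix: channel values at offsets -w..w around
# each frame, edges replicated
window_features <- function(rec, channels, w) {
  n <- nrow(rec)
  idx <- seq_len(n)
  cols <- vector("list", length(channels) * (2L * w + 1L))
  nm <- character(length(cols))
  j <- 0L
  for (ch in channels) {
    x <- rec[[ch]]
    for (k in -w:w) {
      j <- j + 1L
      cols[[j]] <- x[pmin(pmax(idx + k, 1L), n)]
      nm[j] <- sprintf("%s_%+d", ch, k)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Train the foot-strike detector
#'
#' Fits a class-weighted random forest that labels every frame of a
#' preprocessed recording as strike / no-strike from a sliding window
#' of sensor context. Positive frames are up-weighted by the
#' negative-to-positive frame ratio so the ~3-4% strike frames are not
#' swamped. Training is deterministic given the seed.
#'
#' @param training List of labelled walks, each a list with elements
#'   `recording` (preprocessed [imu_recording()]) and `labels`
#'   ([frame_labels()]).
#' @param config A [detector_config()].
#' @param seed Integer seed.
#' @return A `footstrike_detector` model.
#' @export
train_detector <- function(training, config = detector_config(),
                           seed = 1L) {
  if (length(training) == 0) stop("training set must be non-empty")
  for (tr in training) {
    miss <- setdiff(config$channels, names(tr$recording))
    if (length(miss) > 0) {
      stop("training recording lacks channel(s): ",
           paste(miss, collapse = ", "))
    }
    if (length(tr$labels) != nrow(tr$recording)) {
      stop("labels must align with their recording")
    }
  }
  x <- do.call(rbind, lapply(training, function(tr) {
    window_features(tr$recording, config$channels, config$window_frames)
  }))
  y <- unlist(lapply(training, function(tr) as.integer(tr$labels)))
  model <- list(config = config, seed = as.integer(seed),
                constant = NULL, forest = NULL)
  if (length(unique(y)) == 1L) {
    model$constant <- unique(y)   # degenerate but valid
    return(structure(model, class = "footstrike_detector"))
  }
  w_pos <- sum(y == 0L) / sum(y == 1L)
  wts <- ifelse(y == 1L, w_pos, 1)
  df <- as.data.frame(x)
  df$.strike <- factor(y, levels = c(0L, 1L))
  model$forest <- ranger::ranger(
    dependent.variable.name = ".strike", data = df,
    num.trees = config$num_trees, probability = TRUE,
    case.weights = wts, seed = as.integer(seed), num.threads = 1,
    verbose = FALSE)
  structure(model, class = "footstrike_detector")
}

#' @export
print.footstrike_detector <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<footstrike_detector> constant model (always %d)\n",
                x$constant))
  } else {
    cat(sprintf(
      "<footstrike_detector> %d trees, window +/-%d frames, %d channels\n",
      x$config$num_trees, x$config$window_frames,
      length(x$config$channels)))
  }
  invisible(x)
}

#' Predict per-frame foot-strike labels
#'
#' Applies a trained detector to a recording preprocessed the same way
#' as the training walks. Recordings shorter than the context window
#' are padded by edge replication.
#'
#' @param model A `footstrike_detector` from [train_detector()].
#' @param rec A preprocessed [imu_recording()].
#' @return [frame_labels()], one label per frame.
#' @export
detect_frames <- function(model, rec) {
  stopifnot(inherits(model, "footstrike_detector"))
  miss <- setdiff(model$config$channels, names(rec))
  if (length(miss) > 0) {
    stop("recording lacks channel(s) the model was trained on: ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(model$constant)) {
    return(frame_labels(rep(model$constant, nrow(rec))))
  }
  x <- as.data.frame(window_features(rec, model$config$channels,
                                     model$config$window_frames))
  pr <- predict(model$forest, data = x, num.threads = 1,
                verbose = FALSE)$predictions
  frame_labels(as.integer(pr[, "1"] >= model$config$threshold))
}

#' Save / load a trained detector
#'
#' The model is stored as a versioned binary with a JSON sidecar
#' (`<path>.json`) describing its configuration and seed.
#'
#' @param model A `footstrike_detector`.
#' @param path Output path for the model file.
#' @return `save_detector()`: `path`, invisibly; `load_detector()`: the
#'   model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "footstrike_detector"))
  saveRDS(model, path)
  side <- list(version = model$config$version,
               window_frames = model$config$window_frames,
               channels = model$config$channels,
               num_trees = model$config$num_trees,
               threshold = model$config$threshold,
               seed = model$seed,
               constant = model$constant)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "footstrike_detector")) {
    stop("not a footstrike_detector model file: ", path)
  }
  model
}
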