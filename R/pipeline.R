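# Pipeline configuration (flat key-value file, schema-versioned) and
# the end-to-end orchestration: preprocess -> detect -> postprocess ->
# features -> aggregate -> classify.

config_fields <- function() {
  c("schema_version", "sample_rate", "filter_order", "filter_cutoff",
    "lock_clamp_min", "lock_clamp_max", "gap_factor",
    "tolerance_frames", "turn_threshold", "n_fft", "vert_window",
    "cfs", "num_trees", "seed")
}

#' Pipeline configuration
#'
#' All tunable constants of the pipeline in one validated object:
#' sampling and filtering (50 Hz, 4th-order 4 Hz zero-lag low-pass),
#' locking-period clamp, the 1.5x missed-step gap factor, the +/-2
#' frame event-matching tolerance, the turn-exclusion threshold,
#' spectral padding, the CFS variant and forest settings, and the seed.
#'
#' @param sample_rate Uniform rate in Hz (default 50).
#' @param filter_order,filter_cutoff Butterworth order and cutoff in Hz
#'   (defaults 4 and 4).
#' @param lock_clamp_min,lock_clamp_max Locking-period clamp in frames
#'   (defaults 10, 35).
#' @param gap_factor Missed-step gap multiplier (default 1.5).
#' @param tolerance_frames Event-matching tolerance (default 2).
#' @param turn_threshold Turn rotation-rate threshold in degrees/s
#'   (default 45).
#' @param n_fft Spectral zero-padding length (default 256).
#' @param vert_window AP-to-vertical peak pairing window in s
#'   (default 0.1).
#' @param cfs Feature-class correlation variant; only `"pearson"` is
#'   implemented.
#' @param num_trees Random-forest size (default 100).
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_rate = 50, filter_order = 4L,
                            filter_cutoff = 4, lock_clamp_min = 10L,
                            lock_clamp_max = 35L, gap_factor = 1.5,
                            tolerance_frames = 2L, turn_threshold = 45,
                            n_fft = 256L, vert_window = 0.1,
                            cfs = "pearson", num_trees = 100L,
                            seed = 1L) {
  cfg <- list(schema_version = 1L, sample_rate = sample_rate,
              filter_order = as.integer(filter_order),
              filter_cutoff = filter_cutoff,
              lock_clamp_min = as.integer(lock_clamp_min),
              lock_clamp_max = as.integer(lock_clamp_max),
              gap_factor = gap_factor,
              tolerance_frames = as.integer(tolerance_frames),
              turn_threshold = turn_threshold,
              n_fft = as.integer(n_fft), vert_window = vert_window,
              cfs = cfs, num_trees = as.integer(num_trees),
              seed = as.integer(seed))
  if (cfg$sample_rate <= 0) stop("sample_rate must be positive")
  if (cfg$filter_cutoff <= 0 ||
      cfg$filter_cutoff >= cfg$sample_rate / 2) {
    stop("filter_cutoff must lie in (0, sample_rate/2)")
  }
  if (cfg$lock_clamp_min < 1 ||
      cfg$lock_clamp_max < cfg$lock_clamp_min) {
    stop("invalid locking-period clamp")
  }
  if (cfg$gap_factor <= 1) stop("gap_factor must exceed 1")
  if (!cfg$cfs %in% "pearson") stop("unknown cfs variant: ", cfg$cfs)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Flat `key: value` text format with a schema version; unknown keys
#' are rejected so a config file round-trips losslessly.
#'
#' @param path File path.
#' @return `read_config()`: a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")), "")
  unknown <- setdiff(keys, config_fields())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- as.list(setNames(vals, keys))
  args$schema_version <- NULL
  num <- setdiff(names(args), "cfs")
  args[num] <- lapply(args[num], as.numeric)
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, format, "")), path)
  invisible(path)
}

#' Run the full fall-risk pipeline on a cohort
#'
#' For every cohort member: preprocess (resample + zero-lag filter),
#' detect foot strikes (a trained detector when supplied, otherwise the
#' rule-based labeller), post-process into cleaned events, compute the
#' 62-feature step table and the 248-feature participant vector; then
#' classify the cohort with per-fold CFS + random forest under
#' leave-one-out cross-validation.
#'
#' @param config A [pipeline_config()].
#' @param cohort List of members as produced by [generate_cohort()]
#'   (each with `recording`, `fall_risk`, `participant_id`).
#' @param detector Optional `footstrike_detector`; `NULL` uses the
#'   rule-based labeller.
#' @param out_dir Optional directory for intermediate CSV/JSON
#'   artifacts.
#' @return List with `report` ([loocv_random_forest()] output),
#'   `participants` (cohort feature table) and `events` (per-member
#'   cleaned events).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort,
                         detector = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  spec <- filter_spec(config$filter_order, config$filter_cutoff)
  clamp <- c(config$lock_clamp_min, config$lock_clamp_max)
  vectors <- vector("list", length(cohort))
  events_out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    m <- cohort[[i]]
    prec <- preprocess_recording(m$recording, config$sample_rate, spec)
    labels <- if (is.null(detector)) {
      ev <- label_rule_based(prec, vert_window = config$vert_window)
      events_to_labels(ev, nrow(prec))
    } else {
      detect_frames(detector, prec)
    }
    lock <- tryCatch(compute_locking_period(prec, clamp = clamp),
                     error = function(e) clamp[1])
    ev <- postprocess(labels, prec, gap_factor = config$gap_factor,
                      lock = lock)
    tab <- step_features(prec, ev, exclude_turns = TRUE,
                         turn_threshold = config$turn_threshold,
                         n_fft = config$n_fft)
    vectors[[i]] <- aggregate_participant(tab, m$fall_risk,
                                          m$participant_id)
    events_out[[i]] <- ev
    if (!is.null(out_dir)) {
      write_events(ev, file.path(out_dir,
                                 paste0(m$participant_id, "_events.csv")))
      write_step_features(tab, file.path(
        out_dir, paste0(m$participant_id, "_steps.csv")))
    }
  }
  participants <- bind_participants(vectors)
  report <- loocv_random_forest(participants,
                                num_trees = config$num_trees,
                                seed = config$seed)
  if (!is.null(out_dir)) {
    write.csv(participants, file.path(out_dir, "participants.csv"),
              row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    write_config(config, file.path(out_dir, "config.txt"))
  }
  list(report = report, participants = participants,
       events = events_out)
}
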