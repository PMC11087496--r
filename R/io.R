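# Plain-text interchange: CSV recordings and event tables, JSON metadata
# and reports, YAML pipeline configuration.

#' Write a walk trace to disk
#'
#' One CSV per trace holding all sensor channels (columns `time`,
#' `sensor_1`, ...), a JSON sidecar with sampling rate, sensor positions
#' and the noise-reference interval, and CSVs for the ground-truth
#' annotations and the distractor log.
#'
#' @param trace An `fg_trace`.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Invisibly, the paths written.
#' @export
write_trace <- function(trace, dir, name = "trace") {
  stopifnot(inherits(trace, "fg_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- trace$recordings[[1]]$sampling_rate
  n <- length(trace$recordings[[1]]$samples)
  mat <- data.frame(time = (seq_len(n) - 1) / fs)
  for (r in trace$recordings) {
    mat[[paste0("sensor_", r$sensor_id)]] <-
      c(r$samples, rep(NA_real_, n - length(r$samples)))[seq_len(n)]
  }
  rec_path <- file.path(dir, paste0(name, "_recordings.csv"))
  utils::write.csv(mat, rec_path, row.names = FALSE)
  meta <- list(
    sampling_rate = fs,
    positions = vapply(trace$recordings, function(r) r$position, numeric(1)),
    noise_reference = trace$recordings[[1]]$noise_reference,
    noise_sd = trace$noise_sd)
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  ann <- trace$annotations
  ann_df <- data.frame(step = seq_along(ann$strike_times),
                       strike_time = ann$strike_times,
                       contact_type = ann$contact_types,
                       peak_force = ann$peak_force,
                       x_position = ann$x_position,
                       foot = ann$foot)
  ann_path <- file.path(dir, paste0(name, "_annotations.csv"))
  utils::write.csv(ann_df, ann_path, row.names = FALSE)
  dis_path <- file.path(dir, paste0(name, "_distractors.csv"))
  utils::write.csv(ann$distractors, dis_path, row.names = FALSE)
  invisible(c(rec_path, meta_path, ann_path, dis_path))
}

#' Read a multi-sensor recording CSV written by [write_trace()]
#'
#' @param rec_path Path to the `*_recordings.csv` file.
#' @param meta_path Path to the JSON sidecar; defaults to the matching
#'   `*_meta.json`.
#' @return List of `fg_recording`, one per sensor column.
#' @export
read_recordings <- function(rec_path,
                            meta_path = sub("_recordings\\.csv$",
                                            "_meta.json", rec_path)) {
  mat <- utils::read.csv(rec_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cols <- grep("^sensor_", names(mat), value = TRUE)
  lapply(seq_along(cols), function(i) {
    sensor_recording(mat[[cols[i]]], meta$sampling_rate,
                     sensor_id = as.integer(sub("sensor_", "", cols[i])),
                     noise_reference = meta$noise_reference,
                     position = meta$positions[i])
  })
}

#' Write a detected-impulse event table
#'
#' CSV with one row per accepted footstep impulse: sensor id, onset,
#' offset, index in trace, clipping flag.
#'
#' @param impulses List of `fg_impulse` from [segment_footsteps()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_impulse_events <- function(impulses, path) {
  df <- do.call(rbind, lapply(impulses, function(im) {
    data.frame(sensor_id = im$sensor_id, onset = im$onset_time,
               offset = im$offset_time, index = im$index_in_trace,
               clipped = im$clipped)
  }))
  if (is.null(df)) {
    df <- data.frame(sensor_id = integer(0), onset = numeric(0),
                     offset = numeric(0), index = integer(0),
                     clipped = logical(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the simulator, detection pipeline, feature
#' extraction and hierarchical model, with their package defaults; the
#' structure the YAML configuration file must follow.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    generator = list(n_subjects = 12, stage_distribution = rep(1 / 6, 6),
                     traces_per_subject = c(4, 6),
                     steps_per_trace = c(8, 12), noise_sd = 0.02,
                     natural_frequency = 22, damping_ratio = 0.12,
                     attenuation_rate = 0.1,
                     sampling_rate = 500),
    detection = list(window = 0.1, threshold_sd = 3, min_duration = 0.2,
                     max_duration = 0.6, min_run = 3, gap_max = 2.0),
    wavelet = list(band = c(5, 25), gamma = 3, beta = 8, voices = 12,
                   smooth = 0.1),
    strikes = list(min_separation = 0.25, prominence_factor = 2),
    features = list(n_spectrum_bins = 40, n_psd_bands = 3,
                    n_representative_bins = 10),
    model = default_hier_config(),
    n_sensors = 2,
    seed = 1
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check <- function(user, ref, prefix = "") {
    bad <- setdiff(names(user), names(ref))
    if (length(bad) > 0) {
      stop("unknown configuration key(s): ",
           paste0(prefix, bad, collapse = ", "))
    }
    for (k in names(user)) {
      if (is.list(ref[[k]]) && is.list(user[[k]])) {
        check(user[[k]], ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check(user, cfg)
  utils::modifyList(cfg, user)
}

#' Write an evaluation report as JSON
#'
#' @param report List (e.g. from [run_recovery_experiment()]); matrices are
#'   converted to row-wise lists.
#' @param path Output path.
#' @param seed Seed recorded alongside for provenance.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path, seed = NULL) {
  out <- list(
    seed = seed,
    accuracy = report$accuracy,
    macro_f1 = report$macro_f1,
    per_class_f1 = report$f1$per_class,
    confusion_counts = as.data.frame(report$confusion$counts),
    cohort_stages = report$cohort_stages)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
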