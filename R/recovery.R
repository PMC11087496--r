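# End-to-end glue: recordings -> footstep/trace features -> hierarchical
# training -> evaluation reports; the synthetic recovery experiment.

#' Train a contact classifier from simulator calibration pulses
#'
#' Generates labeled heel/midfoot/toe footstep transients (the synthetic
#' counterpart of a labeled lab walking session) and trains the
#' initial-contact SVM on their normalized spectra.
#'
#' @param n_per_class Training pulses per contact class.
#' @param floor A [floor_model()].
#' @param sampling_rate Sampling rate in Hz.
#' @param n_bins Spectrum bins (must match downstream use).
#' @param seed Integer seed.
#' @return An `fg_contact_model`.
#' @export
calibration_contact_model <- function(n_per_class = 40,
                                      floor = floor_model(),
                                      sampling_rate = 500, n_bins = 40,
                                      seed = 1) {
  labels <- rep(c("heel", "midfoot", "toe"), each = n_per_class)
  with_seed_if(seed, {
    spectra <- t(vapply(labels, function(l) {
      footstep_spectrum(
        generate_footstep_pulse(l, floor = floor,
                                sampling_rate = sampling_rate),
        n_bins = n_bins, sampling_rate = sampling_rate)
    }, numeric(n_bins)))
    train_contact_classifier(spectra, labels, seed = seed)
  })
}

# Pick the `n` sensors with the highest total energy for a trace.
best_sensors <- function(trace, n = 1) {
  en <- vapply(trace$recordings, function(r) sum(r$samples^2), numeric(1))
  order(en, decreasing = TRUE)[seq_len(min(n, length(en)))]
}

#' Extract step- and trace-level features from one recording
#'
#' Full single-sensor pipeline: noise estimation, impulse detection and
#' footstep filtering, segmentation, wavelet strike picking, and
#' symptom-based plus signal-based feature computation. Step times are
#' taken from the wavelet strike sequence when it matches the accepted
#' footstep count (one impulse per footstep), falling back to candidate
#' onsets otherwise; the last footstep inherits the preceding interval.
#'
#' @param recording An `fg_recording`.
#' @param contact_model An `fg_contact_model` for toe-contact probabilities.
#' @param band Floor-resonance band for the wavelet envelope.
#' @param min_steps Minimum accepted footsteps for a usable trace.
#' @return List with `steps` (feature matrix, one row per footstep),
#'   `features` (named trace feature vector), and `n_footsteps`; or `NULL`
#'   if fewer than `min_steps` footsteps survive filtering.
#' @export
extract_trace_features <- function(recording, contact_model,
                                   band = c(5, 25), min_steps = 3) {
  noise <- estimate_noise_stats(recording)
  cands <- detect_impulses(recording, noise)
  acc <- filter_footstep_impulses(cands)
  if (nrow(acc) < min_steps) return(NULL)
  impulses <- segment_footsteps(recording, acc)
  env <- wavelet_band_envelope(recording, band = band)
  strikes <- detect_foot_strikes(env)
  n <- length(impulses)
  timing <- if (length(strikes) == n) strikes else acc$onset
  if (length(timing) < 2) return(NULL)
  intervals <- diff(timing)
  step_time <- c(intervals, intervals[length(intervals)])

  spectra <- t(vapply(impulses, footstep_spectrum, numeric(40),
                      n_bins = 40))
  toe_probs <- predict_contact_probs(contact_model, spectra)
  toe_p <- if ("toe" %in% colnames(toe_probs)) toe_probs[, "toe"] else
    numeric(n)

  stats4 <- t(vapply(impulses, basic_stats, numeric(4)))
  domf_s <- vapply(impulses, dominant_frequency, numeric(1),
                   phase = "strike")
  domf_o <- vapply(impulses, dominant_frequency, numeric(1), phase = "off")
  psd3 <- t(vapply(impulses, psd_band_powers, numeric(3)))

  steps <- cbind(step_time = step_time, toe_prob = toe_p,
                 sensor = recording$sensor_id,
                 mean = stats4[, "mean"], sd = stats4[, "sd"],
                 skewness = stats4[, "skewness"],
                 kurtosis = stats4[, "kurtosis"],
                 dom_freq_strike = domf_s, dom_freq_off = domf_o,
                 psd1 = psd3[, 1], psd2 = psd3[, 2], psd3 = psd3[, 3])
  steps[!is.finite(steps)] <- 0

  energies <- vapply(impulses, footstep_energy, numeric(1))
  rep_fs <- representative_footstep(impulses)
  feats <- c(symmetry = symmetry_score(vapply(impulses, x90_amplitude,
                                              numeric(1))),
             step_time_var = step_time_variability(intervals),
             cadence = cadence(timing),
             energy_var = energy_variability(energies))
  rpsd <- footstep_spectrum(rep_fs, n_bins = 10)
  names(rpsd) <- paste0("rpsd", 1:10)
  feats <- c(feats, rpsd)
  feats[!is.finite(feats)] <- 0
  list(steps = steps, features = feats, n_footsteps = n)
}

#' Extract hierarchical features for a whole cohort
#'
#' Runs [extract_trace_features()] over every subject's traces. Each
#' (walking pass, sensor) pair yields one trace sample, mirroring a
#' deployment where each sensor records the pass independently; the
#' per-subject trace-sample counts are then equalized with
#' [rebalance_subjects()].
#'
#' @param cohort An [generate_cohort()] result.
#' @param contact_model An `fg_contact_model`.
#' @param n_sensors Number of best (highest-energy) sensors per pass.
#' @param rebalance Equalize per-subject trace counts to the cohort median.
#' @param seed Seed for the rebalancing resampler.
#' @return List of person feature bundles for [train_hierarchical()].
#' @export
extract_cohort_features <- function(cohort, contact_model, n_sensors = 2,
                                    rebalance = TRUE, seed = 1) {
  stopifnot(inherits(cohort, "fg_cohort"))
  persons <- lapply(cohort$subjects, function(sub) {
    traces <- list()
    for (tr in sub$traces) {
      for (s in best_sensors(tr, n_sensors)) {
        ft <- extract_trace_features(tr$recordings[[s]], contact_model)
        if (!is.null(ft)) {
          traces[[length(traces) + 1]] <-
            list(steps = ft$steps, features = ft$features)
        }
      }
    }
    list(id = sub$id, stage = sub$stage, biometrics = sub$biometrics,
         traces = traces)
  })
  keep <- vapply(persons, function(p) length(p$traces) >= 1, logical(1))
  persons <- persons[keep]
  if (rebalance) {
    lists <- rebalance_subjects(lapply(persons, function(p) p$traces),
                                seed = seed)
    for (k in seq_along(persons)) persons[[k]]$traces <- lists[[k]]
  }
  persons
}

#' Synthetic recovery experiment
#'
#' Generates a labeled cohort, runs the complete pipeline (contact
#' calibration, detection, feature extraction, rebalancing, hierarchical
#' training) and reports per-level accuracies, macro F-1 and the
#' person-level confusion matrix. Fully reproducible under a seed.
#'
#' @param config Optional overrides: `n_subjects`, `stage_distribution`,
#'   `traces_per_subject`, `steps_per_trace`, `noise_sd`, `n_sensors`,
#'   plus any [train_hierarchical()] configuration under `model`.
#' @param seed Integer seed.
#' @return List with `accuracy` (step/trace/person), `macro_f1`,
#'   `confusion`, the trained `model`, and the evaluation details.
#' @export
run_recovery_experiment <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(n_subjects = 12, stage_distribution = rep(1 / 6, 6),
         traces_per_subject = c(4, 6), steps_per_trace = c(8, 12),
         noise_sd = 0.02, n_sensors = 2, model = list()),
    config)
  seed <- as.integer(seed)
  cohort <- generate_cohort(
    cfg$n_subjects, cfg$stage_distribution,
    traces_per_subject_range = cfg$traces_per_subject,
    steps_per_trace_range = cfg$steps_per_trace,
    noise_sd = cfg$noise_sd, seed = seed)
  contact_model <- calibration_contact_model(seed = seed + 1L)
  features <- extract_cohort_features(cohort, contact_model,
                                      n_sensors = cfg$n_sensors,
                                      seed = seed + 2L)
  model <- train_hierarchical(features, config = cfg$model,
                              seed = seed + 3L)
  ev <- evaluate_hierarchical(model, features)
  f1 <- f1_scores(ev$person_predictions, ev$person_truth, classes = 0:5)
  cm <- confusion_matrix(ev$person_predictions, ev$person_truth,
                         classes = 0:5)
  list(accuracy = list(step = ev$step, trace = ev$trace, person = ev$person),
       macro_f1 = f1$macro_f1, confusion = cm, f1 = f1,
       model = model, evaluation = ev, cohort_stages =
         vapply(cohort$subjects, function(s) s$stage, numeric(1)))
}
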