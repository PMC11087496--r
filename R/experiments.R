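# Seeded experiment harnesses over the simulator: detection scoring,
# timing-recovery error measurement, and symptom-trend summaries.

# Match detected onsets to annotated strikes (both sorted): greedy nearest
# within `tol` seconds, one-to-one.
match_events <- function(detected, truth, tol) {
  used <- logical(length(detected))
  match_idx <- rep(NA_integer_, length(truth))
  for (i in seq_along(truth)) {
    d <- abs(detected - truth[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol) {
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  match_idx
}

#' Detection precision/recall experiment
#'
#' Generates seeded walk traces across all stages with superimposed
#' distractor transients, calibrates the noise so the weakest footstep sits
#' at the requested amplitude SNR, runs threshold detection plus footstep
#' filtering on the mid-walkway sensor, and scores accepted impulses
#' against the simulator annotations (onset tolerance 0.12 s, one
#' half-window beyond the detector's resolution).
#'
#' @param n_traces Number of traces.
#' @param snr Amplitude SNR of the weakest footstep (linear ratio).
#' @param seed Integer seed.
#' @param steps_range Footsteps per trace.
#' @return List with `precision`, `recall`, `distractors_rejected`
#'   (fraction of injected distractors absent from the accepted set), and
#'   counts.
#' @export
run_detection_experiment <- function(n_traces = 50, snr = 10, seed = 1,
                                     steps_range = c(8, 12)) {
  with_seed_if(seed, {
    tp <- 0; fp <- 0; fn <- 0
    n_distract <- 0; distract_hit <- 0
    for (i in seq_len(n_traces)) {
      stage <- (i - 1) %% 6
      prof <- gait_profile_for_stage(stage, seed = sample.int(2^31 - 2, 1))
      n_steps <- sample(seq(steps_range[1], steps_range[2]), 1)
      tr_seed <- sample.int(2^31 - 2, 1)
      clean <- generate_walk_trace(prof, n_steps, noise_sd = 0,
                                   seed = tr_seed)
      mid <- mean(range(clean$annotations$x_position))
      pos <- vapply(clean$recordings, function(r) r$position, numeric(1))
      s <- which.min(abs(pos - mid))
      nsd <- min(annotated_step_peaks(clean, s)) / snr
      trace <- generate_walk_trace(prof, n_steps, noise_sd = nsd,
                                   seed = tr_seed)
      trace <- inject_distractors(
        trace, c("isolated_impulse", "long_transient", "short_blip"),
        seed = sample.int(2^31 - 2, 1))
      rec <- trace$recordings[[s]]
      acc <- filter_footstep_impulses(
        detect_impulses(rec, estimate_noise_stats(rec)))
      truth <- trace$annotations$strike_times
      m <- match_events(acc$onset, truth, tol = 0.12)
      tp <- tp + sum(!is.na(m))
      fn <- fn + sum(is.na(m))
      fp <- fp + (nrow(acc) - sum(!is.na(m)))
      dis <- trace$annotations$distractors
      n_distract <- n_distract + nrow(dis)
      for (k in seq_len(nrow(dis))) {
        overlap <- any(acc$onset < dis$offset[k] &
                         acc$offset > dis$onset[k])
        distract_hit <- distract_hit + overlap
      }
    }
    list(precision = tp / (tp + fp), recall = tp / (tp + fn),
         distractors_rejected = 1 - distract_hit / max(n_distract, 1),
         n_traces = n_traces, n_footsteps = tp + fn)
  })
}

#' Step-time and cadence recovery experiment
#'
#' Generates seeded traces across all stages at a given dB SNR (weakest
#' footstep), extracts strike sequences with the wavelet-envelope picker,
#' and measures the step-time MAE over matched consecutive strike pairs and
#' the cadence MAE per trace against the simulator annotations.
#'
#' @param n_traces Number of traces.
#' @param snr_db Amplitude SNR of the weakest footstep in dB; `Inf` for
#'   noise-free.
#' @param seed Integer seed.
#' @param steps_range Footsteps per trace.
#' @return List with `step_time_mae` (s), `cadence_mae` (steps/min),
#'   `count_error_rate` (fraction of traces with a miscounted strike
#'   total), and sample sizes.
#' @export
run_timing_experiment <- function(n_traces = 100, snr_db = 10, seed = 1,
                                  steps_range = c(8, 12)) {
  with_seed_if(seed, {
    st_err <- c(); cad_err <- c(); miscount <- 0
    for (i in seq_len(n_traces)) {
      stage <- (i - 1) %% 6
      prof <- gait_profile_for_stage(stage, seed = sample.int(2^31 - 2, 1))
      n_steps <- sample(seq(steps_range[1], steps_range[2]), 1)
      tr_seed <- sample.int(2^31 - 2, 1)
      clean <- generate_walk_trace(prof, n_steps, noise_sd = 0,
                                   seed = tr_seed)
      mid <- mean(range(clean$annotations$x_position))
      pos <- vapply(clean$recordings, function(r) r$position, numeric(1))
      s <- which.min(abs(pos - mid))
      nsd <- if (is.finite(snr_db)) {
        min(annotated_step_peaks(clean, s)) / 10^(snr_db / 20)
      } else 0
      trace <- generate_walk_trace(prof, n_steps, noise_sd = nsd,
                                   seed = tr_seed)
      env <- wavelet_band_envelope(trace$recordings[[s]])
      strikes <- detect_foot_strikes(env)
      truth <- trace$annotations$strike_times
      if (length(strikes) >= 2) {
        cad_err <- c(cad_err, abs(cadence(strikes) - cadence(truth)))
      }
      if (length(strikes) != length(truth)) miscount <- miscount + 1
      m <- match_events(strikes, truth, tol = 0.2)
      for (k in seq_len(length(truth) - 1)) {
        if (!is.na(m[k]) && !is.na(m[k + 1])) {
          st_err <- c(st_err,
                      abs((strikes[m[k + 1]] - strikes[m[k]]) -
                            (truth[k + 1] - truth[k])))
        }
      }
    }
    list(step_time_mae = mean(st_err), cadence_mae = mean(cad_err),
         count_error_rate = miscount / n_traces,
         n_traces = n_traces, n_step_pairs = length(st_err))
  })
}

#' Symptom-trend experiment across functional stages
#'
#' Generates seeded cohorts of traces per stage, runs the detection +
#' segmentation pipeline, and summarizes the two progression symptoms the
#' generator encodes: the mean symmetry score (expected to decrease with
#' stage) and the mean predicted toe-contact probability (expected to
#' increase with stage).
#'
#' @param traces_per_stage Traces per stage.
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @param contact_model Optional pre-trained `fg_contact_model`.
#' @return data.frame with `stage`, `mean_symmetry`, `mean_toe_prob`.
#' @export
run_symptom_trend_experiment <- function(traces_per_stage = 8,
                                         noise_sd = 0.01, seed = 1,
                                         contact_model = NULL) {
  with_seed_if(seed, {
    if (is.null(contact_model)) {
      contact_model <- calibration_contact_model(
        seed = sample.int(2^31 - 2, 1))
    }
    out <- lapply(0:5, function(stage) {
      sym <- c(); toe <- c()
      for (r in seq_len(traces_per_stage)) {
        prof <- gait_profile_for_stage(stage,
                                       seed = sample.int(2^31 - 2, 1))
        trace <- generate_walk_trace(prof, 10, noise_sd = noise_sd,
                                     seed = sample.int(2^31 - 2, 1))
        mid <- mean(range(trace$annotations$x_position))
        pos <- vapply(trace$recordings, function(r) r$position, numeric(1))
        rec <- trace$recordings[[which.min(abs(pos - mid))]]
        acc <- filter_footstep_impulses(
          detect_impulses(rec, estimate_noise_stats(rec)))
        if (nrow(acc) < 2) next
        imps <- segment_footsteps(rec, acc)
        sym <- c(sym, symmetry_score(vapply(imps, x90_amplitude,
                                            numeric(1))))
        sp <- t(vapply(imps, footstep_spectrum, numeric(40), n_bins = 40))
        pr <- predict_contact_probs(contact_model, sp)
        toe <- c(toe, mean(pr[, "toe"]))
      }
      data.frame(stage = stage, mean_symmetry = mean(sym),
                 mean_toe_prob = mean(toe))
    })
    do.call(rbind, out)
  })
}
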