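# Shared fixtures: all inputs are generated in code at test time.

# Sensor closest to the midpoint of the walk, i.e. the one a deployment
# would rate as best-placed for the pass.
mid_sensor <- function(trace) {
  mid <- mean(range(trace$annotations$x_position))
  pos <- vapply(trace$recordings, function(r) r$position, numeric(1))
  which.min(abs(pos - mid))
}

# Noise SD giving the weakest annotated footstep the requested amplitude
# SNR (linear ratio) at the chosen sensor.
noise_sd_for_snr <- function(clean_trace, sensor, snr) {
  min(annotated_step_peaks(clean_trace, sensor)) / snr
}

# Noise SD for a dB SNR on the weakest footstep.
noise_sd_for_snr_db <- function(clean_trace, sensor, snr_db) {
  noise_sd_for_snr(clean_trace, sensor, 10^(snr_db / 20))
}

# Regenerate a trace with noise calibrated to the clean peaks; identical
# strike structure because the generator draws noise after the gait
# parameters under the same seed.
trace_at_snr <- function(profile, n_steps, seed, snr = NULL,
                         snr_db = NULL, ...) {
  clean <- generate_walk_trace(profile, n_steps, noise_sd = 0, seed = seed,
                               ...)
  s <- mid_sensor(clean)
  nsd <- if (!is.null(snr_db)) noise_sd_for_snr_db(clean, s, snr_db)
         else noise_sd_for_snr(clean, s, snr)
  trace <- generate_walk_trace(profile, n_steps, noise_sd = nsd,
                               seed = seed, ...)
  list(trace = trace, sensor = s, noise_sd = nsd)
}

# Labeled calibration spectra for the contact classifier.
contact_spectra <- function(n_per_class, seed) {
  labels <- rep(c("heel", "midfoot", "toe"), each = n_per_class)
  withr::with_seed(seed, {
    sp <- t(vapply(labels, function(l) {
      footstep_spectrum(generate_footstep_pulse(l), n_bins = 40,
                        sampling_rate = 500)
    }, numeric(40)))
  })
  list(spectra = sp, labels = labels)
}

# Tiny, well-separated cohort feature bundle built directly (no signal
# processing) for fast hierarchical-model tests: per-stage feature means
# with small noise.
toy_cohort_features <- function(n_per_stage = 2, traces_per_subject = 4,
                                steps_per_trace = 10, stages = 0:5,
                                noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    persons <- list()
    id <- 0
    for (stg in stages) {
      for (r in seq_len(n_per_stage)) {
        id <- id + 1
        bio <- biometrics(age = 7 + stg + runif(1), weight = 30 + stg,
                          height = 1.2 + 0.03 * stg,
                          gender = sample(c("male", "female"), 1))
        traces <- lapply(seq_len(traces_per_subject), function(j) {
          base <- c(step_time = 0.5 + 0.05 * stg, toe_prob = stg / 5,
                    sensor = j %% 2 + 1, mean = 0, sd = 0.1 + 0.02 * stg,
                    skewness = 0, kurtosis = 3,
                    dom_freq_strike = 20 + 20 * stg, dom_freq_off = 15,
                    psd1 = 0.5 - 0.05 * stg, psd2 = 0.3,
                    psd3 = 0.2 + 0.05 * stg)
          steps <- t(vapply(seq_len(steps_per_trace), function(i) {
            base + stats::rnorm(length(base), 0, noise)
          }, numeric(length(base))))
          colnames(steps) <- names(base)
          feats <- c(symmetry = 1 - 0.15 * stg,
                     step_time_var = 0.01 + 0.005 * stg,
                     cadence = 110 - 4 * stg, energy_var = 0.1 + 0.05 * stg,
                     setNames(rep(0.1, 10), paste0("rpsd", 1:10)))
          feats[1:4] <- feats[1:4] + stats::rnorm(4, 0, noise / 2)
          list(steps = steps, features = feats)
        })
        persons[[id]] <- list(id = id, stage = stg, biometrics = bio,
                              traces = traces)
      }
    }
    persons
  })
}
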