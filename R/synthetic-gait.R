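# Synthetic gait-vibration simulator: labeled walk traces and cohorts with
# the statistical structure the analysis pipeline assumes.

#' Floor vibration model
#'
#' Parameters of the simulated floor response. Footstep forces excite a
#' lightly damped resonance whose natural frequency sits in the 5-25 Hz band
#' that the symptom extractor later isolates; vibration amplitude decays
#' exponentially with distance from the excitation point.
#'
#' @param natural_frequency Floor natural frequency in Hz, within \[5, 25\].
#' @param damping_ratio Modal damping ratio, in (0, 1).
#' @param attenuation_rate Amplitude decay per meter of travel (>= 0).
#' @return Object of class `fg_floor_model`.
#' @export
floor_model <- function(natural_frequency = 22, damping_ratio = 0.12,
                        attenuation_rate = 0.1) {
  stopifnot(natural_frequency >= 5, natural_frequency <= 25,
            damping_ratio > 0, damping_ratio < 1, attenuation_rate >= 0)
  structure(list(natural_frequency = natural_frequency,
                 damping_ratio = damping_ratio,
                 attenuation_rate = attenuation_rate),
            class = "fg_floor_model")
}

#' Gait profile
#'
#' Person-level gait parameters driving the simulator. `cadence` and the
#' mean inter-strike interval are reciprocal (interval = 60 / cadence);
#' `left_right_amplitude_ratio` scales every second footstep's force so a
#' ratio away from 1 produces the amplitude alternation that lowers the
#' symmetry score; `contact_type_probs` gives the per-step probability of
#' heel, midfoot and toe initial contact.
#'
#' @param cadence Steps per minute (> 0).
#' @param step_time_jitter_sd SD of the inter-strike interval in s (>= 0).
#' @param left_right_amplitude_ratio Force ratio of the weaker to the
#'   stronger side (> 0).
#' @param contact_type_probs Named numeric simplex over
#'   `c("heel", "midfoot", "toe")`.
#' @param force_scale Overall footstep force multiplier (> 0 unless
#'   explicitly silenced).
#' @return Object of class `fg_gait_profile`.
#' @export
gait_profile <- function(cadence = 110, step_time_jitter_sd = 0.01,
                         left_right_amplitude_ratio = 1,
                         contact_type_probs = c(heel = 0.9, midfoot = 0.08,
                                                toe = 0.02),
                         force_scale = 1) {
  stopifnot(cadence > 0, step_time_jitter_sd >= 0,
            left_right_amplitude_ratio > 0, force_scale >= 0)
  p <- contact_type_probs[c("heel", "midfoot", "toe")]
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("contact_type_probs must be a named simplex over heel/midfoot/toe")
  }
  structure(list(cadence = cadence, step_time_jitter_sd = step_time_jitter_sd,
                 left_right_amplitude_ratio = left_right_amplitude_ratio,
                 contact_type_probs = p, force_scale = force_scale),
            class = "fg_gait_profile")
}

#' Sensor layout
#'
#' Positions of the geophones along the walkway and the shared sampling
#' rate. The default mirrors a lab walkway: four sensors spaced 2 m apart
#' at 500 Hz.
#'
#' @param positions Strictly increasing sensor positions in meters.
#' @param sampling_rate Sampling rate in Hz; must satisfy Nyquist for the
#'   highest generated contact frequency (checked downstream).
#' @return Object of class `fg_sensor_layout`.
#' @export
sensor_layout <- function(positions = c(0.5, 2.5, 4.5, 6.5),
                          sampling_rate = 500) {
  stopifnot(length(positions) >= 1, all(diff(positions) > 0),
            sampling_rate > 0)
  structure(list(positions = positions, sampling_rate = sampling_rate),
            class = "fg_sensor_layout")
}

# Dominant frequency of the contact burst per initial-contact type (Hz).
# Larger contact area (heel) -> lower-frequency content; frictional toe
# contact -> higher-frequency content. Stand-in values, overridable.
contact_burst_freqs <- c(heel = 15, midfoot = 60, toe = 120)

# Piecewise envelope of a footstep transient: half-cosine attack, plateau,
# half-cosine release. Sustains window-level detectability for the full
# nominal duration rather than decaying exponentially.
pulse_envelope <- function(t, duration, attack = 0.03, release_start = 0.18) {
  release_start <- min(release_start, duration * 0.6)
  env <- numeric(length(t))
  rise <- t < attack
  env[rise] <- sin(pi * t[rise] / (2 * attack))^2
  hold <- t >= attack & t < release_start
  env[hold] <- 1
  rel <- t >= release_start & t <= duration
  env[rel] <- cos(pi * (t[rel] - release_start) /
                    (2 * (duration - release_start)))^2
  env
}

#' Generate a single footstep transient
#'
#' A footstep is modeled as a short-duration force applied to the floor:
#' the resulting waveform is a windowed floor-resonance response (at the
#' floor's damped natural frequency) plus a decaying contact burst whose
#' dominant frequency is ordered heel < midfoot < toe. The waveform peak is
#' normalized to `force_scale`; a zero force yields an all-zero series.
#'
#' @param contact_type One of `"heel"`, `"midfoot"`, `"toe"`.
#' @param force_scale Peak amplitude of the transient (>= 0).
#' @param floor A [floor_model()].
#' @param sampling_rate Sampling rate in Hz; must exceed twice the contact
#'   burst frequency.
#' @param duration Transient duration in s, within \[0.2, 0.6\].
#' @param seed Optional integer seed (phase/jitter determinism).
#' @return Numeric vector of `round(duration * sampling_rate)` samples.
#' @export
generate_footstep_pulse <- function(contact_type, force_scale = 1,
                                    floor = floor_model(),
                                    sampling_rate = 500, duration = 0.28,
                                    seed = NULL) {
  if (!is.character(contact_type) ||
      !contact_type %in% names(contact_burst_freqs)) {
    stop("unknown contact_type; expected heel, midfoot or toe")
  }
  stopifnot(duration >= 0.2, duration <= 0.6, force_scale >= 0)
  fc <- contact_burst_freqs[[contact_type]]
  if (sampling_rate < 2 * fc) {
    stop("sampling_rate below Nyquist for the contact burst frequency")
  }
  with_seed_if(seed, {
    n <- round(duration * sampling_rate)
    t <- (seq_len(n) - 1) / sampling_rate
    fd <- floor$natural_frequency * sqrt(1 - floor$damping_ratio^2)
    ph1 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    jit <- stats::runif(2, 0.97, 1.03)   # small tonal jitter between steps
    resonance <- sin(2 * pi * fd * jit[1] * t + ph1)
    contact <- 1.5 * sin(2 * pi * fc * jit[2] * t + ph2)
    x <- pulse_envelope(t, duration) * (resonance + contact)
    peak <- max(abs(x))
    if (peak > 0 && force_scale > 0) x * force_scale / peak else x * 0
  })
}

# Stage-conditional generator parameters (stages 0-5). Toe-contact
# probability rises monotonically with stage, the left-right force ratio
# departs monotonically from 1 (lowering the symmetry score), cadence
# follows the increase-then-decrease profile of progressive MD gait, and
# step-time jitter grows with stage.
stage_profile_table <- list(
  cadence = c(104, 112, 118, 121, 107, 91),
  jitter = c(0.010, 0.014, 0.018, 0.022, 0.028, 0.035),
  ratio = c(1.00, 0.88, 0.78, 0.68, 0.58, 0.48),
  force = c(1.00, 0.95, 0.90, 0.85, 0.80, 0.75),
  contact = rbind(
    c(0.88, 0.10, 0.02),
    c(0.65, 0.20, 0.15),
    c(0.45, 0.25, 0.30),
    c(0.30, 0.25, 0.45),
    c(0.15, 0.20, 0.65),
    c(0.05, 0.12, 0.83)
  )
)

#' Gait profile for a functional stage
#'
#' Returns a [gait_profile()] parameterized for a functional stage 0-5:
#' toe-contact probability non-decreasing in stage, left-right amplitude
#' ratio departing from 1 monotonically (so the symmetry score decreases in
#' expectation), and cadence increasing then decreasing across stages. With
#' a seed, cadence and force receive small subject-level perturbations; the
#' contact mix and amplitude ratio stay at their stage values.
#'
#' @param stage Integer stage in `0:5`.
#' @param seed Optional integer seed for subject-level variation.
#' @return An `fg_gait_profile`.
#' @export
gait_profile_for_stage <- function(stage, seed = NULL) {
  if (length(stage) != 1 || !stage %in% 0:5) {
    stop("stage must be a single integer in 0:5")
  }
  i <- stage + 1L
  tab <- stage_profile_table
  with_seed_if(seed, {
    cad <- tab$cadence[i] + if (is.null(seed)) 0 else stats::rnorm(1, 0, 2)
    frc <- max(0.2, tab$force[i] +
                 if (is.null(seed)) 0 else stats::rnorm(1, 0, 0.03))
    gait_profile(
      cadence = cad,
      step_time_jitter_sd = tab$jitter[i],
      left_right_amplitude_ratio = tab$ratio[i],
      contact_type_probs = c(heel = tab$contact[i, 1],
                             midfoot = tab$contact[i, 2],
                             toe = tab$contact[i, 3]),
      force_scale = frc
    )
  })
}

#' Generate a multi-sensor walk trace with ground-truth annotations
#'
#' Synthesizes one walking pass: `n_steps` footstep transients at strike
#' times with Normal(60/cadence, jitter) inter-strike intervals, alternating
#' step amplitudes scaled by the left-right ratio, a footstep source moving
#' linearly along the walkway, per-sensor exponential distance attenuation,
#' additive Gaussian noise, and a leading pure-noise segment of at least 2 s
#' for noise-reference estimation.
#'
#' @param profile A [gait_profile()].
#' @param n_steps Number of footsteps (>= 0; 0 yields noise/silence only).
#' @param layout A [sensor_layout()].
#' @param floor A [floor_model()].
#' @param noise_sd Additive Gaussian noise SD in volts (>= 0).
#' @param seed Optional integer seed.
#' @param lead_time Seconds of signal before the first strike (>= 2).
#' @param tail_time Seconds of signal after the last transient.
#' @param step_length Walker advance per step in meters.
#' @param lateral_offset Perpendicular sensor distance from the walking
#'   line in meters.
#' @return Object of class `fg_trace`: `recordings` (one `fg_recording` per
#'   sensor) and `annotations` (strike times, contact types, per-step peak
#'   force, foot side, plus an initially empty distractor log).
#' @export
generate_walk_trace <- function(profile, n_steps, layout = sensor_layout(),
                                floor = floor_model(), noise_sd = 0,
                                seed = NULL, lead_time = 4, tail_time = 4,
                                step_length = 0.6, lateral_offset = 0.5) {
  stopifnot(inherits(profile, "fg_gait_profile"), n_steps >= 0,
            noise_sd >= 0, lead_time >= 2)
  if (length(layout$positions) == 0) stop("empty sensor layout")
  fs <- layout$sampling_rate
  with_seed_if(seed, {
    mean_dt <- 60 / profile$cadence
    if (n_steps >= 2) {
      dts <- stats::rnorm(n_steps - 1, mean_dt, profile$step_time_jitter_sd)
      # floor on the interval keeps consecutive transients from overlapping
      dts <- pmax(dts, max(0.42, 0.3 * mean_dt))
    } else dts <- numeric(0)
    strikes <- lead_time + c(0, cumsum(dts))[seq_len(n_steps)]
    pulse_dur <- 0.28
    total <- lead_time + (if (n_steps > 0) max(strikes) - lead_time else 0) +
      pulse_dur + tail_time
    n_total <- round(total * fs)

    contacts <- if (n_steps > 0) {
      sample(names(profile$contact_type_probs), n_steps, replace = TRUE,
             prob = profile$contact_type_probs)
    } else character(0)
    side <- rep(c("left", "right"), length.out = n_steps)
    amp <- profile$force_scale *
      ifelse(side == "left", 1, profile$left_right_amplitude_ratio) *
      exp(stats::rnorm(n_steps, 0, 0.05))
    x_start <- min(layout$positions) - 0.5
    x_pos <- x_start + step_length * (seq_len(n_steps) - 1)

    pulses <- lapply(seq_len(n_steps), function(i) {
      generate_footstep_pulse(contacts[i], force_scale = 1, floor = floor,
                              sampling_rate = fs, duration = pulse_dur)
    })

    recordings <- lapply(seq_along(layout$positions), function(s) {
      x <- if (noise_sd > 0) stats::rnorm(n_total, 0, noise_sd) else
        numeric(n_total)
      for (i in seq_len(n_steps)) {
        d <- sqrt((layout$positions[s] - x_pos[i])^2 + lateral_offset^2)
        gain <- amp[i] * exp(-floor$attenuation_rate * d)
        i0 <- round(strikes[i] * fs) + 1
        idx <- i0:(i0 + length(pulses[[i]]) - 1)
        keep <- idx <= n_total
        x[idx[keep]] <- x[idx[keep]] + gain * pulses[[i]][keep]
      }
      sensor_recording(x, fs, sensor_id = s,
                       noise_reference = c(1L, as.integer(2 * fs)),
                       position = layout$positions[s])
    })
    # noise realizations differ per sensor; amplitudes/timing are shared
    structure(
      list(recordings = recordings,
           annotations = list(
             strike_times = strikes,
             contact_types = contacts,
             peak_force = amp,
             x_position = x_pos,
             foot = side,
             stage_label = NA_integer_,
             biometrics = NULL,
             distractors = data.frame(onset = numeric(0), offset = numeric(0),
                                      kind = character(0),
                                      stringsAsFactors = FALSE)),
           profile = profile, layout = layout, floor = floor,
           noise_sd = noise_sd),
      class = "fg_trace")
  })
}

#' @export
print.fg_trace <- function(x, ...) {
  cat(sprintf("<fg_trace> %d footsteps, %d sensors, %.2f s @ %g Hz\n",
              length(x$annotations$strike_times), length(x$recordings),
              recording_duration(x$recordings[[1]]),
              x$recordings[[1]]$sampling_rate))
  invisible(x)
}

#' Annotated per-step peak amplitudes at a sensor
#'
#' Simulator oracle: the clean peak amplitude each annotated footstep
#' produces at one sensor (force times distance attenuation), before noise.
#' Useful for setting noise levels relative to the weakest footstep.
#'
#' @param trace An `fg_trace`.
#' @param sensor_id Sensor index into the trace's layout.
#' @param lateral_offset Same perpendicular offset used at generation time.
#' @return Numeric vector of peak amplitudes, one per footstep.
#' @export
annotated_step_peaks <- function(trace, sensor_id = 1,
                                 lateral_offset = 0.5) {
  stopifnot(inherits(trace, "fg_trace"))
  ann <- trace$annotations
  pos <- trace$layout$positions[sensor_id]
  d <- sqrt((pos - ann$x_position)^2 + lateral_offset^2)
  ann$peak_force * exp(-trace$floor$attenuation_rate * d)
}

distractor_waveform <- function(kind, fs) {
  spec <- switch(kind,
    isolated_impulse = list(dur = 0.40, freq = 18),
    long_transient = list(dur = 1.00, freq = 10),
    short_blip = list(dur = 0.06, freq = 80),
    stop("unknown distractor kind: ", kind))
  n <- round(spec$dur * fs)
  t <- (seq_len(n) - 1) / fs
  sin(pi * t / spec$dur)^2 * sin(2 * pi * spec$freq * t)
}

#' Superimpose non-footstep distractor transients
#'
#' Appends distractor transients (with surrounding noise matching the
#' recording's noise floor) to a trace or a single recording: an isolated
#' footstep-like impulse (a run of fewer than 3 impulses), a long transient
#' (> 0.6 s, e.g. a door closing), and/or a short blip (< 0.2 s, e.g. an
#' item dropping). Their intervals are logged so that detection filters can
#' be scored against them. An empty `kinds` returns the input unchanged.
#'
#' @param x An `fg_trace` or `fg_recording`.
#' @param kinds Subset of
#'   `c("isolated_impulse", "long_transient", "short_blip")`.
#' @param seed Optional integer seed.
#' @param amplitude Distractor peak amplitude; default matches the largest
#'   absolute sample of the input.
#' @return The input with distractors superimposed and logged (in
#'   `annotations$distractors` for traces, attribute `"distractors"` for
#'   recordings).
#' @export
inject_distractors <- function(x, kinds, seed = NULL, amplitude = NULL) {
  kinds <- as.character(kinds)
  allowed <- c("isolated_impulse", "long_transient", "short_blip")
  if (!all(kinds %in% allowed)) stop("unknown distractor kind")
  if (length(kinds) == 0) return(x)
  if (inherits(x, "fg_recording")) {
    return(inject_distractors_recording(x, kinds, seed, amplitude))
  }
  stopifnot(inherits(x, "fg_trace"))
  with_seed_if(seed, {
    fs <- x$recordings[[1]]$sampling_rate
    amp <- amplitude %||% max(1e-3, max(vapply(
      x$recordings, function(r) max(abs(r$samples)), numeric(1))))
    gap <- 3.5   # > consecutiveness gap, so appended transients are isolated
    t0 <- recording_duration(x$recordings[[1]])
    log <- x$annotations$distractors
    waves <- lapply(kinds, distractor_waveform, fs = fs)
    onsets <- numeric(length(kinds))
    tcur <- t0
    for (i in seq_along(kinds)) {
      onsets[i] <- tcur + gap
      tcur <- onsets[i] + length(waves[[i]]) / fs
    }
    n_new <- round((tcur + 2 - t0) * fs)
    x$recordings <- lapply(x$recordings, function(r) {
      nsd <- stats::sd(r$samples[r$noise_reference[1]:r$noise_reference[2]])
      ext <- if (nsd > 0) stats::rnorm(n_new, 0, nsd) else numeric(n_new)
      for (i in seq_along(kinds)) {
        j0 <- round((onsets[i] - t0) * fs) + 1
        idx <- j0:(j0 + length(waves[[i]]) - 1)
        ext[idx] <- ext[idx] + amp * waves[[i]]
      }
      r$samples <- c(r$samples, ext)
      r
    })
    x$annotations$distractors <- rbind(log, data.frame(
      onset = onsets,
      offset = onsets + vapply(waves, length, integer(1)) / fs,
      kind = kinds, stringsAsFactors = FALSE))
    x
  })
}

inject_distractors_recording <- function(rec, kinds, seed, amplitude) {
  with_seed_if(seed, {
    fs <- rec$sampling_rate
    amp <- amplitude %||% max(1e-3, max(abs(rec$samples)))
    t0 <- recording_duration(rec)
    waves <- lapply(kinds, distractor_waveform, fs = fs)
    onsets <- numeric(length(kinds))
    tcur <- t0
    for (i in seq_along(kinds)) {
      onsets[i] <- tcur + 3.5
      tcur <- onsets[i] + length(waves[[i]]) / fs
    }
    n_new <- round((tcur + 2 - t0) * fs)
    nsd <- stats::sd(rec$samples[rec$noise_reference[1]:rec$noise_reference[2]])
    ext <- if (nsd > 0) stats::rnorm(n_new, 0, nsd) else numeric(n_new)
    for (i in seq_along(kinds)) {
      j0 <- round((onsets[i] - t0) * fs) + 1
      idx <- j0:(j0 + length(waves[[i]]) - 1)
      ext[idx] <- ext[idx] + amp * waves[[i]]
    }
    rec$samples <- c(rec$samples, ext)
    attr(rec, "distractors") <- rbind(
      attr(rec, "distractors") %||%
        data.frame(onset = numeric(0), offset = numeric(0),
                   kind = character(0), stringsAsFactors = FALSE),
      data.frame(onset = onsets,
                 offset = onsets + vapply(waves, length, integer(1)) / fs,
                 kind = kinds, stringsAsFactors = FALSE))
    rec
  })
}

# Normative-percent bands used when inverting the functional scale to draw
# a run time consistent with an assigned stage (strictly inside each band).
stage_percent_bands <- rbind(
  c(102, 125), c(81, 98), c(61, 78), c(50.5, 59), c(40.5, 49), c(30.5, 39)
)

#' Generate a labeled synthetic cohort
#'
#' Draws subjects with stage labels allocated by largest remainder from
#' `stage_distribution`, stage-conditional gait profiles, biometrics whose
#' simulated 100-m run time reproduces the assigned stage exactly under the
#' functional scale (round-trip by construction), and a variable number of
#' walk traces per subject to exercise sample rebalancing.
#'
#' @param n_subjects Number of subjects.
#' @param stage_distribution Simplex over stages 0-5.
#' @param traces_per_subject_range Length-2 integer range of traces per
#'   subject.
#' @param steps_per_trace_range Length-2 integer range of footsteps per
#'   trace.
#' @param layout,floor,noise_sd Passed to [generate_walk_trace()].
#' @param seed Optional integer seed; fixed seeds give identical cohorts.
#' @return Object of class `fg_cohort`: list of subjects, each with `id`,
#'   `stage`, `biometrics`, `run_time_100m`, `profile` and `traces`.
#' @export
generate_cohort <- function(n_subjects, stage_distribution = rep(1 / 6, 6),
                            traces_per_subject_range = c(5, 10),
                            steps_per_trace_range = c(8, 12),
                            layout = sensor_layout(), floor = floor_model(),
                            noise_sd = 0.02, seed = NULL) {
  stopifnot(n_subjects >= 1, length(stage_distribution) == 6,
            all(stage_distribution >= 0),
            abs(sum(stage_distribution) - 1) < 1e-8,
            length(traces_per_subject_range) == 2)
  # largest-remainder allocation of subjects to stages
  raw <- n_subjects * stage_distribution
  counts <- base::floor(raw)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  stages <- rep(0:5, counts)
  with_seed_if(seed, {
    subjects <- lapply(seq_len(n_subjects), function(k) {
      stage <- stages[k]
      sub_seed <- sample.int(2^31 - 2, 1)
      withr::with_seed(sub_seed, {
        age <- stats::runif(1, 6 + 0.9 * stage, 11 + 0.9 * stage)
        height <- 0.95 + 0.045 * (age - 5) + stats::rnorm(1, 0, 0.03)
        bmi <- stats::runif(1, 15, 19)
        weight <- bmi * height^2
        gender <- sample(c("male", "female"), 1)
        bio <- biometrics(age, weight, height, gender)
        numerator <- 36.72 - 1.51 * age + 0.26 * bmi
        pct <- stats::runif(1, stage_percent_bands[stage + 1, 1],
                            stage_percent_bands[stage + 1, 2])
        run_time <- numerator / pct * 100
        profile <- gait_profile_for_stage(stage, seed = sample.int(2^31 - 2, 1))
        n_traces <- sample(seq(traces_per_subject_range[1],
                               traces_per_subject_range[2]), 1)
        traces <- lapply(seq_len(n_traces), function(j) {
          tr <- generate_walk_trace(
            profile,
            n_steps = sample(seq(steps_per_trace_range[1],
                                 steps_per_trace_range[2]), 1),
            layout = layout, floor = floor, noise_sd = noise_sd)
          tr$annotations$stage_label <- stage
          tr$annotations$biometrics <- bio
          tr
        })
        list(id = k, stage = stage, biometrics = bio, run_time_100m = run_time,
             profile = profile, traces = traces)
      })
    })
    structure(list(subjects = subjects, layout = layout, floor = floor,
                   noise_sd = noise_sd),
              class = "fg_cohort")
  })
}

#' @export
print.fg_cohort <- function(x, ...) {
  st <- vapply(x$subjects, function(s) s$stage, numeric(1))
  cat(sprintf("<fg_cohort> %d subjects, stages: %s\n", length(x$subjects),
              paste(table(factor(st, levels = 0:5)), collapse = "/")))
  invisible(x)
}
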