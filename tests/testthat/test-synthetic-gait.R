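# Synthetic gait-vibration generator: pulses, profiles, traces, cohorts.

test_that("footstep pulse basics: duration, silence, determinism, errors", {
  p <- generate_footstep_pulse("heel", seed = 1)
  expect_true(length(p) / 500 >= 0.2 && length(p) / 500 <= 0.6)
  expect_equal(max(abs(p)), 1)   # peak normalized to force_scale
  expect_identical(generate_footstep_pulse("toe", force_scale = 0, seed = 2),
                   rep(0, length(p)))
  expect_identical(generate_footstep_pulse("midfoot", seed = 7),
                   generate_footstep_pulse("midfoot", seed = 7))
  expect_error(generate_footstep_pulse("flat"), "contact_type")
  expect_error(generate_footstep_pulse("toe", sampling_rate = 100),
               "Nyquist")
})

test_that("contact-type dominant frequencies are ordered heel<mid<toe", {
  withr::with_seed(11, {
    doms <- replicate(40, {
      c(h = dominant_frequency(generate_footstep_pulse("heel"),
                               sampling_rate = 500),
        m = dominant_frequency(generate_footstep_pulse("midfoot"),
                               sampling_rate = 500),
        t = dominant_frequency(generate_footstep_pulse("toe"),
                               sampling_rate = 500))
    })
  })
  expect_true(all(doms["t", ] > doms["h", ]))
  expect_true(mean(doms["m", ] > doms["h", ]) >= 0.95)
  expect_true(mean(doms["t", ] > doms["m", ]) >= 0.95)
})

test_that("stage profiles follow the documented symptom trends", {
  profs <- lapply(0:5, gait_profile_for_stage)
  toe <- vapply(profs, function(p) p$contact_type_probs[["toe"]],
                numeric(1))
  expect_true(all(diff(toe) >= 0))
  expect_lt(toe[1], 0.1)
  expect_gt(toe[6], toe[2])
  ratio <- vapply(profs, function(p) p$left_right_amplitude_ratio,
                  numeric(1))
  expect_identical(ratio[1], 1)
  expect_true(all(diff(abs(1 - ratio)) > 0))   # monotone departure from 1
  cad <- vapply(profs, function(p) p$cadence, numeric(1))
  pk <- which.max(cad)
  expect_true(pk > 1 && pk < 6)                # increase then decrease
  expect_true(all(diff(cad[1:pk]) > 0) && all(diff(cad[pk:6]) < 0))
  expect_error(gait_profile_for_stage(6))
  expect_error(gait_profile_for_stage(-1))
})

test_that("walk traces honor cadence, alternation and attenuation", {
  prof <- gait_profile(cadence = 120, step_time_jitter_sd = 0)
  tr <- generate_walk_trace(prof, 8, noise_sd = 0, seed = 3)
  expect_equal(diff(tr$annotations$strike_times), rep(0.5, 7))
  # a footstep is at least as strong at the nearer sensor
  lay <- tr$layout
  fl <- tr$floor
  for (i in c(1, 4, 8)) {
    t0 <- tr$annotations$strike_times[i]
    idx <- round(t0 * 500):round((t0 + 0.3) * 500)
    d <- abs(vapply(tr$recordings, function(r) r$position, numeric(1)) -
               tr$annotations$x_position[i])
    near <- which.min(d); far <- which.max(d)
    pk <- vapply(tr$recordings, function(r) max(abs(r$samples[idx])),
                 numeric(1))
    expect_gte(pk[near], pk[far])
  }
  # leading pure-noise segment of at least 2 s
  nr <- tr$recordings[[1]]$noise_reference
  expect_gte((nr[2] - nr[1] + 1) / 500, 2)
  expect_true(all(abs(tr$recordings[[1]]$samples[nr[1]:nr[2]]) == 0))
})

test_that("silent traces and empty layouts behave as contracted", {
  prof <- gait_profile()
  tr <- generate_walk_trace(prof, 0, noise_sd = 0, seed = 1)
  expect_true(all(vapply(tr$recordings,
                         function(r) all(r$samples == 0), logical(1))))
  expect_error(generate_walk_trace(prof, -1))
})

test_that("annotated peaks match the generated waveform peaks", {
  prof <- gait_profile_for_stage(2, seed = 9)
  tr <- generate_walk_trace(prof, 6, noise_sd = 0, seed = 31)
  s <- mid_sensor(tr)
  rec <- tr$recordings[[s]]
  pred <- annotated_step_peaks(tr, s)
  for (i in seq_len(6)) {
    t0 <- tr$annotations$strike_times[i]
    idx <- round(t0 * 500):round((t0 + 0.3) * 500)
    expect_equal(max(abs(rec$samples[idx])), pred[i], tolerance = 0.02)
  }
})

test_that("distractor injection logs intervals and is identity on empty", {
  prof <- gait_profile()
  tr <- generate_walk_trace(prof, 5, noise_sd = 0.01, seed = 2)
  expect_identical(inject_distractors(tr, character(0)), tr)
  tr2 <- inject_distractors(
    tr, c("isolated_impulse", "long_transient", "short_blip"), seed = 5)
  log <- tr2$annotations$distractors
  expect_equal(nrow(log), 3)
  recording_len <- length(tr$recordings[[1]]$samples) / 500
  expect_true(all(log$onset > recording_len))
  durs <- log$offset - log$onset
  expect_lt(durs[log$kind == "short_blip"], 0.2)
  expect_gt(durs[log$kind == "long_transient"], 0.6)
  expect_error(inject_distractors(tr, "doorbell"))
})

test_that("cohorts round-trip stage labels through the functional scale", {
  cohort <- generate_cohort(12, rep(1 / 6, 6),
                            traces_per_subject_range = c(2, 3),
                            steps_per_trace_range = c(4, 5),
                            noise_sd = 0, seed = 17)
  recovered <- vapply(cohort$subjects, function(s) {
    functional_stage(s$biometrics, s$run_time_100m)$stage
  }, integer(1))
  expect_identical(recovered,
                   vapply(cohort$subjects, function(s) as.integer(s$stage),
                          integer(1)))
  counts <- vapply(cohort$subjects, function(s) length(s$traces),
                   integer(1))
  expect_true(all(counts >= 2 & counts <= 3))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(4, traces_per_subject_range = c(2, 2),
                       steps_per_trace_range = c(4, 4), seed = 5)
  b <- generate_cohort(4, traces_per_subject_range = c(2, 2),
                       steps_per_trace_range = c(4, 4), seed = 5)
  expect_identical(a, b)
})
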