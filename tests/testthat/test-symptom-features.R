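# Wavelet envelope, strike picking, and symptom-based gait features.

test_that("band envelope isolates the floor-resonance band", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  env0 <- wavelet_band_envelope(numeric(2000), sampling_rate = fs)
  expect_true(all(env0$values == 0))
  env15 <- wavelet_band_envelope(sin(2 * pi * 15 * t), sampling_rate = fs)
  env100 <- wavelet_band_envelope(sin(2 * pi * 100 * t), sampling_rate = fs)
  mid <- 500:1500
  expect_gt(mean(env15$values[mid]), 5 * mean(env100$values[mid]))
  expect_true(all(env15$values >= 0))
  expect_error(wavelet_band_envelope(rnorm(100), band = c(30, 20),
                                     sampling_rate = fs))
})

test_that("envelope peaks align with annotated strikes on clean traces", {
  prof <- gait_profile_for_stage(0, seed = 1)
  tr <- generate_walk_trace(prof, 10, noise_sd = 0, seed = 42)
  s <- mid_sensor(tr)
  strikes <- detect_foot_strikes(wavelet_band_envelope(tr$recordings[[s]]),
                                 refine = "onset")
  truth <- tr$annotations$strike_times
  expect_length(strikes, length(truth))
  expect_true(all(abs(strikes - truth) <= 0.06))
})

test_that("strike picking: flat envelopes, close peaks, separation", {
  flat <- structure(list(values = numeric(1000), sampling_rate = 500),
                    class = "fg_envelope")
  expect_length(detect_foot_strikes(flat), 0)
  # two peaks 0.1 s apart with 0.25 s separation: larger one kept
  v <- numeric(1000)
  v[300] <- 1; v[350] <- 0.6
  v <- floorgait:::moving_average(v, 15)
  env <- structure(list(values = v, sampling_rate = 500),
                   class = "fg_envelope")
  st <- detect_foot_strikes(env, refine = "peak")
  expect_length(st, 1)
  expect_lt(abs(st - 299 / 500), 0.03)
})

test_that("strike sequence recovery at 20 dB SNR is exact and precise", {
  prof <- gait_profile(cadence = 110, step_time_jitter_sd = 0.015)
  fx <- trace_at_snr(prof, 10, seed = 61, snr_db = 20)
  env <- wavelet_band_envelope(fx$trace$recordings[[fx$sensor]])
  strikes <- detect_foot_strikes(env, refine = "onset")
  truth <- fx$trace$annotations$strike_times
  expect_length(strikes, length(truth))
  expect_true(all(abs(strikes - truth) <= 0.06))
})

test_that("step times, cadence and variability follow their formulas", {
  expect_equal(step_times(c(0.0, 0.5, 1.1)), c(0.5, 0.6))
  expect_length(step_times(1.5), 0)
  expect_equal(step_times(seq(0, 4, by = 0.5)), rep(0.5, 8))
  expect_equal(cadence(seq(0, 4.5, by = 0.5)), 120)
  expect_equal(cadence(c(2, 3)), 60)
  expect_equal(cadence(c(10, 10.5, 11, 11.5)),
               cadence(c(0, 0.5, 1, 1.5)))     # translation invariance
  expect_error(cadence(1))
  expect_equal(step_time_variability(c(0.4, 0.6)), sqrt(0.02))
  expect_equal(step_time_variability(rep(0.5, 6)), 0)
  expect_equal(step_time_variability(2 * c(0.4, 0.5, 0.7)),
               2 * step_time_variability(c(0.4, 0.5, 0.7)))
  expect_error(step_time_variability(0.5))
})

test_that("symmetry score matches its closed form and invariances", {
  expect_equal(symmetry_score(c(2, 2, 2)), 1)
  expect_equal(symmetry_score(c(1, 3)), 0)
  expect_equal(symmetry_score(c(2, 2, 4)), 1 - mean(c(0, 2 / 3)))
  x <- c(1.2, 0.7, 1.1, 0.6)
  expect_equal(symmetry_score(10 * x), symmetry_score(x))   # scaling
  expect_equal(symmetry_score(rev(x[1:2])), symmetry_score(x[1:2]))
  expect_error(symmetry_score(c(0, 0, 1)), "zero amplitude")
  expect_error(symmetry_score(1))
  # alternating amplitudes a, ra: score = 1 - 2(1-r)/(1+r)
  r <- 0.6
  expect_equal(symmetry_score(rep(c(1, r), 5)), 1 - 2 * (1 - r) / (1 + r))
})

test_that("footstep spectra are unit-sum, localized, scale-invariant", {
  fs <- 500
  t <- seq(0, 0.4, by = 1 / fs)
  tone <- sin(2 * pi * 20 * t) * sin(pi * t / 0.4)^2
  sp <- footstep_spectrum(tone, sampling_rate = fs)
  expect_equal(sum(sp), 1)
  bin20 <- base::floor(20 / 250 * 40) + 1
  expect_gt(sum(sp[(bin20 - 1):(bin20 + 1)]), 0.8)
  expect_equal(footstep_spectrum(5 * tone, sampling_rate = fs), sp)
  expect_error(footstep_spectrum(numeric(0), sampling_rate = fs))
})

test_that("contact classifier separates synthetic contact types", {
  cs <- contact_spectra(30, seed = 21)
  idx_tr <- unlist(lapply(0:2, function(k) k * 30 + 1:20))
  idx_te <- setdiff(seq_len(90), idx_tr)
  model <- train_contact_classifier(cs$spectra[idx_tr, ],
                                    cs$labels[idx_tr], seed = 1)
  probs <- predict_contact_probs(model, cs$spectra[idx_te, ])
  expect_equal(unname(rowSums(probs)), rep(1, length(idx_te)),
               tolerance = 1e-9)
  acc <- mean(model$classes[max.col(probs)] == cs$labels[idx_te])
  expect_gte(acc, 0.95)
  # toe probability semantics on clean spectra
  toe_sp <- cs$spectra[75, ]; heel_sp <- cs$spectra[5, ]
  expect_gt(toe_contact_probability(model, toe_sp), 0.5)
  expect_lt(toe_contact_probability(model, heel_sp), 0.5)
})

test_that("permuted labels bring the contact classifier to chance", {
  cs <- contact_spectra(70, seed = 22)
  withr::with_seed(9, perm <- sample(cs$labels))
  idx_tr <- unlist(lapply(0:2, function(k) k * 70 + 1:20))
  idx_te <- setdiff(seq_len(210), idx_tr)
  model <- train_contact_classifier(cs$spectra[idx_tr, ], perm[idx_tr],
                                    seed = 2)
  probs <- predict_contact_probs(model, cs$spectra[idx_te, ])
  acc <- mean(model$classes[max.col(probs)] == perm[idx_te])
  expect_lt(abs(acc - 1 / 3), 0.1)
})

test_that("classifier input contracts are enforced", {
  cs <- contact_spectra(6, seed = 23)
  expect_error(train_contact_classifier(cs$spectra[1:6, ],
                                        cs$labels[1:6]), "2 contact")
  expect_error(train_contact_classifier(cs$spectra[c(1:4, 7:10), ],
                                        cs$labels[c(1:4, 7:10)]),
               "5 examples")
  model <- train_contact_classifier(cs$spectra, cs$labels, seed = 3)
  expect_error(predict_contact_probs(model, rep(0.1, 10)), "bin count")
})
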