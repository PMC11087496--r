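# Impulse detection, footstep filtering, denoising, rebalancing.

test_that("noise statistics: moments and Parseval-consistent spectrum", {
  zero <- sensor_recording(numeric(1000), 500)
  nz <- estimate_noise_stats(zero)
  expect_equal(nz$mean, 0)
  expect_equal(nz$sd, 0)
  withr::with_seed(1, {
    x <- c(rnorm(5000, 0, 0.1), rnorm(500, 0, 0.1))
    rec <- sensor_recording(x, 500, noise_reference = c(1, 5000))
  })
  ns <- estimate_noise_stats(rec)
  expect_true(ns$sd > 0.095 && ns$sd < 0.105)
  ref <- rec$samples[1:5000]
  expect_equal(sum(ns$spectrum$power), mean((ref - mean(ref))^2),
               tolerance = 0.01)
  expect_true(all(ns$spectrum$power >= 0))
  short <- sensor_recording(rnorm(600), 500, noise_reference = c(1, 300))
  expect_error(estimate_noise_stats(short), "1 s")
})

test_that("detector finds injected pulses and stays quiet on noise", {
  withr::with_seed(2, {
    fs <- 500
    x <- rnorm(10 * fs, 0, 0.01)
    ons <- 3 + (0:4) * 0.5
    pulse <- generate_footstep_pulse("heel", seed = 4)
    for (t0 in ons) {
      idx <- round(t0 * fs) + seq_along(pulse)
      x[idx] <- x[idx] + 0.1 * pulse   # 10x the noise sd
    }
    rec <- sensor_recording(x, fs, noise_reference = c(1, 2 * fs))
  })
  noise <- estimate_noise_stats(rec)
  cand <- detect_impulses(rec, noise)
  expect_equal(nrow(cand), 5)
  expect_true(all(abs(cand$onset - ons) <= 0.1))
  expect_true(!is.unsorted(cand$onset))
  # pure noise: at most 1 spurious candidate per 60 s at the 3-sd rule
  withr::with_seed(3, {
    quiet <- sensor_recording(rnorm(60 * 500, 0, 0.01), 500,
                              noise_reference = c(1, 1000))
  })
  expect_lte(nrow(detect_impulses(quiet, estimate_noise_stats(quiet))), 1)
  # all-zero recording: no candidates even with the degenerate threshold
  zero <- sensor_recording(numeric(5000), 500)
  expect_equal(nrow(detect_impulses(zero, estimate_noise_stats(zero))), 0)
})

test_that("footstep filtering enforces duration and consecutiveness", {
  mk <- function(onsets, dur) data.frame(onset = onsets,
                                         offset = onsets + dur)
  # one isolated plausible candidate: run of 1 < 3
  expect_equal(nrow(filter_footstep_impulses(mk(5, 0.3))), 0)
  # four candidates spaced 0.5 s: all accepted with indices 1..4
  acc <- filter_footstep_impulses(mk(c(1, 1.5, 2, 2.5), 0.3))
  expect_equal(acc$index_in_trace, 1:4)
  # an overlong candidate inside a run is rejected, the rest survive
  cand <- rbind(mk(c(1, 1.5), 0.3), mk(2, 1.0), mk(c(2.5, 3, 3.5), 0.3))
  cand <- cand[order(cand$onset), ]
  acc <- filter_footstep_impulses(cand)
  expect_equal(nrow(acc), 5)
  expect_false(any(acc$offset - acc$onset > 0.6))
  # a 2 s gap still counts as consecutive; beyond it the run breaks
  acc <- filter_footstep_impulses(mk(c(1, 3, 5), 0.3))
  expect_equal(nrow(acc), 3)
  expect_equal(nrow(filter_footstep_impulses(mk(c(1, 3.5, 6), 0.3))), 0)
})

test_that("footstep filtering is idempotent", {
  withr::with_seed(8, {
    onsets <- sort(runif(20, 0, 30))
    cand <- data.frame(onset = onsets,
                       offset = onsets + runif(20, 0.05, 1.2))
  })
  once <- filter_footstep_impulses(cand)
  twice <- filter_footstep_impulses(once)
  expect_identical(once, twice)
})

test_that("lowpass filter attenuates out-of-band tones, passes DC", {
  fs <- 25600
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 100 * t) + sin(2 * pi * 2000 * t) + 0.5
  rec <- sensor_recording(x, fs, noise_reference = c(1, fs))
  out <- lowpass_filter(rec, cutoff = 500)
  pow <- function(sig, f0) {
    p <- Mod(stats::fft(sig))^2
    fr <- (seq_along(sig) - 1) * fs / length(sig)
    sum(p[abs(fr - f0) < 5])
  }
  expect_gt(10 * log10(pow(x, 2000) / pow(out$samples, 2000)), 40)
  expect_gt(pow(out$samples, 100) / pow(x, 100), 0.9)
  expect_equal(mean(out$samples), mean(x), tolerance = 0.01)   # DC
  # at or below Nyquist-matching rates the operation is the identity
  rec500 <- sensor_recording(rnorm(1000), 500)
  expect_identical(lowpass_filter(rec500, cutoff = 500), rec500)
})

test_that("downsampling preserves in-band content at the target rate", {
  fs <- 4000
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  rec <- sensor_recording(x, fs, noise_reference = c(1, fs))
  out <- downsample_recording(rec, 500)
  expect_equal(out$sampling_rate, 500)
  expect_equal(length(out$samples), ceiling(length(x) / 8))
  expect_equal(dominant_frequency(out$samples[100:900], "strike",
                                  sampling_rate = 500), 20,
               tolerance = 2)
})

test_that("wiener gains: identity at zero noise, bounded, SNR-improving", {
  fs <- 500
  withr::with_seed(5, {
    clean_tr <- generate_walk_trace(gait_profile(), 6, noise_sd = 0,
                                    seed = 77)
    s <- mid_sensor(clean_tr)
    clean <- clean_tr$recordings[[s]]$samples
    nsd <- max(abs(clean)) / 10^(0 / 20) / 3   # roughly 10 dB overall
    noisy <- clean + rnorm(length(clean), 0, nsd)
  })
  rec <- sensor_recording(noisy, fs, noise_reference = c(1, 2 * fs))
  noise <- estimate_noise_stats(rec)
  den <- wiener_denoise(rec, noise)
  err_in <- sum((noisy - clean)^2)
  err_out <- sum((den$samples - clean)^2)
  expect_lt(err_out, err_in)       # closer to the clean signal
  # zero noise spectrum: unit gain, output equals input
  zero_noise <- estimate_noise_stats(
    sensor_recording(c(numeric(fs), clean), fs,
                     noise_reference = c(1, fs)))
  passthrough <- wiener_denoise(rec, zero_noise)
  expect_equal(passthrough$samples, rec$samples, tolerance = 1e-9)
  # per-bin output power never exceeds input power
  p_in <- Mod(stats::fft(rec$samples))^2
  p_out <- Mod(stats::fft(den$samples))^2
  expect_true(all(p_out <= p_in * (1 + 1e-8)))
})

test_that("wiener gain is at most 1/2 where noise dominates", {
  # white noise twice as strong as the signal in every bin
  withr::with_seed(9, {
    fs <- 500
    sig <- rnorm(4 * fs, 0, 0.05)
    noise_ref <- rnorm(4 * fs, 0, 0.1)
    rec <- sensor_recording(c(noise_ref, sig), fs,
                            noise_reference = c(1, 4 * fs))
  })
  ns <- estimate_noise_stats(rec)
  den <- wiener_denoise(rec, ns)
  # overall power ratio far below half when N >= S everywhere
  expect_lt(sum(den$samples[(4 * 500 + 1):(8 * 500)]^2) /
              sum(rec$samples[(4 * 500 + 1):(8 * 500)]^2), 0.5)
})

test_that("segmentation slices the recording and flags clipping", {
  withr::with_seed(6, {
    rec <- sensor_recording(rnorm(3000, 0, 0.05), 500)
  })
  imp <- data.frame(onset = c(1, 3), offset = c(1.4, 3.4),
                    index_in_trace = 1:2)
  segs <- segment_footsteps(rec, imp)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$samples,
               rec$samples[(base::floor(1 * 500) + 1):ceiling(1.4 * 500)])
  expect_equal(vapply(segs, function(s) s$onset_time, numeric(1)),
               c(1, 3))
  expect_false(any(vapply(segs, function(s) s$clipped, logical(1))))
  expect_error(segment_footsteps(rec, data.frame(onset = 5.8,
                                                 offset = 6.5)),
               "out of bounds")
})

test_that("rebalancing equalizes counts to the cohort median", {
  lists <- list(a = 1:10, b = 1:20, c = 1:30)
  out <- rebalance_subjects(lists, seed = 1)
  expect_equal(unname(vapply(out, length, integer(1))), rep(20L, 3))
  expect_identical(out$b, 1:20)                    # at median: untouched
  expect_true(all(out$c %in% 1:30) && !anyDuplicated(out$c))
  expect_true(all(out$a %in% 1:10))                # bootstrap resample
  # even cohort: interpolated median, rounded
  out2 <- rebalance_subjects(list(1:4, 1:6), seed = 2)
  expect_equal(unname(vapply(out2, length, integer(1))), c(5L, 5L))
  # equal counts: unchanged
  eq <- list(1:5, 6:10)
  expect_identical(rebalance_subjects(eq, seed = 3), eq)
  # deterministic under seed
  expect_identical(rebalance_subjects(lists, seed = 9),
                   rebalance_subjects(lists, seed = 9))
})
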