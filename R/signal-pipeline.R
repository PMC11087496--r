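# Footstep impulse detection, non-footstep rejection and denoising.

#' Noise statistics from a pure-noise reference segment
#'
#' Computes the mean, standard deviation and periodogram of the recording's
#' pure-noise reference. The spectrum is the two-sided periodogram of the
#' mean-centered reference, normalized so that `sum(power)` equals the
#' population variance of the reference (discrete Parseval identity).
#'
#' @param recording An [sensor_recording()] whose noise reference spans at
#'   least 1 s.
#' @return Object of class `fg_noise_stats`: `mean`, `sd`, and `spectrum`
#'   (data.frame with `freq` in Hz over `[0, fs)` and non-negative `power`),
#'   plus `n_ref` and `sampling_rate`.
#' @export
estimate_noise_stats <- function(recording) {
  stopifnot(inherits(recording, "fg_recording"))
  nr <- recording$noise_reference
  ref <- recording$samples[nr[1]:nr[2]]
  fs <- recording$sampling_rate
  if (length(ref) < fs) stop("noise reference must span at least 1 s")
  centered <- ref - mean(ref)
  n <- length(ref)
  power <- Mod(stats::fft(centered))^2 / n^2
  structure(
    list(mean = mean(ref), sd = stats::sd(ref),
         spectrum = data.frame(freq = (seq_len(n) - 1) * fs / n,
                               power = power),
         n_ref = n, sampling_rate = fs),
    class = "fg_noise_stats")
}

#' Detect candidate impulse intervals
#'
#' Slides a 0.1-s window over the recording (overlapping, default stride of
#' a fifth of a window) and computes the mean absolute amplitude per window;
#' windows whose statistic exceeds `noise$mean + threshold_sd * noise$sd`
#' are merged into maximal candidate intervals `[onset, offset)` (union of
#' the super-threshold windows). The rectified mean is used because the raw
#' mean of a zero-centered oscillation is near zero; the overlapping stride
#' makes interval durations insensitive to window-grid alignment. With a
#' degenerate noise reference (`sd == 0`) an absolute floor threshold of
#' `abs_floor * full_scale` applies.
#'
#' @param recording An `fg_recording` longer than one window.
#' @param noise An [estimate_noise_stats()] result.
#' @param window Window length in s.
#' @param stride Window stride in s (defaults to `window / 5`).
#' @param threshold_sd Number of noise SDs above the noise mean.
#' @param abs_floor Relative absolute floor used when `noise$sd == 0`.
#' @param full_scale Full-scale amplitude of the acquisition chain.
#' @return data.frame with `onset`, `offset` (s from recording start,
#'   half-open) and `duration`, sorted by onset.
#' @export
detect_impulses <- function(recording, noise, window = 0.1, stride = NULL,
                            threshold_sd = 3, abs_floor = 1e-6,
                            full_scale = 1) {
  stopifnot(inherits(recording, "fg_recording"),
            inherits(noise, "fg_noise_stats"))
  fs <- recording$sampling_rate
  wlen <- max(1L, round(window * fs))
  slen <- max(1L, round((stride %||% (window / 5)) * fs))
  x <- abs(recording$samples)
  if (length(x) <= wlen) stop("recording shorter than one window")
  starts <- seq(1L, length(x) - wlen + 1L, by = slen)
  csum <- c(0, cumsum(x))
  stat <- (csum[starts + wlen] - csum[starts]) / wlen
  thr <- noise$mean + threshold_sd * noise$sd
  if (noise$sd == 0) thr <- max(thr, abs_floor * full_scale)
  hot <- which(stat > thr)
  if (length(hot) == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0)))
  }
  # merge overlapping/adjacent hot windows into maximal intervals
  on <- (starts[hot] - 1) / fs
  off <- on + wlen / fs
  brk <- c(TRUE, on[-1] > off[-length(off)] + 1e-9)
  grp <- cumsum(brk)
  out <- data.frame(
    onset = tapply(on, grp, min),
    offset = tapply(off, grp, max))
  out$duration <- out$offset - out$onset
  rownames(out) <- NULL
  out[order(out$onset), , drop = FALSE]
}

#' Keep footstep-consistent impulse candidates
#'
#' Applies the two footstep plausibility rules: candidates whose duration
#' lies outside `[min_duration, max_duration]` are dropped first, then runs
#' of fewer than `min_run` consecutive candidates (consecutive = inter-onset
#' gap of at most `gap_max` seconds) are dropped, because isolated transients
#' such as a door closing do not recur the way a walking pass does.
#' Accepted candidates get `index_in_trace` 1..N. The operation is
#' idempotent.
#'
#' @param candidates data.frame from [detect_impulses()], sorted by onset.
#' @param min_duration,max_duration Accepted duration band in s.
#' @param min_run Minimum number of consecutive candidates.
#' @param gap_max Maximum inter-onset gap (s) for two candidates to count as
#'   consecutive.
#' @return The accepted subset with an `index_in_trace` column.
#' @export
filter_footstep_impulses <- function(candidates, min_duration = 0.2,
                                     max_duration = 0.6, min_run = 3,
                                     gap_max = 2.0) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0 || is.unsorted(candidates$onset)) {
    if (nrow(candidates) > 0) stop("candidates must be sorted by onset")
  }
  dur <- candidates$offset - candidates$onset
  tol <- 1e-9
  keep <- candidates[dur >= min_duration - tol & dur <= max_duration + tol, ,
                     drop = FALSE]
  if (nrow(keep) > 0) {
    gap <- c(Inf, diff(keep$onset))
    run_id <- cumsum(gap > gap_max)
    run_len <- ave(run_id, run_id, FUN = length)
    keep <- keep[run_len >= min_run, , drop = FALSE]
  }
  keep$index_in_trace <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}

#' Lowpass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth lowpass used to strip sensory
#' noise above the gait-relevant band before feature extraction. Recordings
#' already sampled at or below twice the cutoff (e.g. 500 Hz lab data with
#' the default 500 Hz cutoff) pass through unchanged. The forward-backward
#' pass avoids onset-time bias, which matters because onsets feed the step
#' time estimate.
#'
#' @param recording An `fg_recording`.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Butterworth order (per pass).
#' @return The recording with filtered samples.
#' @export
lowpass_filter <- function(recording, cutoff = 500, order = 4) {
  stopifnot(inherits(recording, "fg_recording"), cutoff > 0)
  fs <- recording$sampling_rate
  if (fs <= 2 * cutoff) return(recording)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  recording$samples <- as.numeric(
    signal::filtfilt(bf, recording$samples))
  recording
}

#' Downsample a high-rate recording
#'
#' Hospital-grade acquisitions (e.g. 25600 Hz) carry little gait-relevant
#' power above 250 Hz; this lowpass-filters and decimates to `target_rate`
#' so feature extraction runs at the common lab rate.
#'
#' @param recording An `fg_recording` whose rate is an integer multiple of
#'   `target_rate`.
#' @param target_rate Output sampling rate in Hz.
#' @return The downsampled recording (noise reference rescaled).
#' @export
downsample_recording <- function(recording, target_rate = 500) {
  stopifnot(inherits(recording, "fg_recording"))
  fs <- recording$sampling_rate
  if (fs <= target_rate) return(recording)
  k <- fs / target_rate
  if (abs(k - round(k)) > 1e-8) {
    stop("sampling rate must be an integer multiple of target_rate")
  }
  k <- as.integer(round(k))
  filtered <- lowpass_filter(recording, cutoff = 0.45 * target_rate)
  idx <- seq(1, length(filtered$samples), by = k)
  nr <- pmax(1L, as.integer(ceiling(recording$noise_reference / k)))
  sensor_recording(filtered$samples[idx], target_rate,
                   sensor_id = recording$sensor_id,
                   noise_reference = pmin(nr, length(idx)),
                   position = recording$position)
}

#' Wiener (spectral subtraction) denoising
#'
#' Attenuates each frequency bin by the gain
#' `max(0, 1 - N(f) / |X(f)|^2)`, where `N(f)` is the expected noise power
#' at that bin extrapolated from the reference-segment periodogram. Gains
#' are clamped to `[0, 1]`, so output power never exceeds input power in any
#' bin; a zero noise spectrum leaves the signal untouched.
#'
#' @param recording An `fg_recording`.
#' @param noise An [estimate_noise_stats()] result from the same sensor.
#' @param smooth_bins Width (bins) of the running average applied to the
#'   reference periodogram before interpolation, to tame its variance.
#' @return The recording with denoised samples.
#' @export
wiener_denoise <- function(recording, noise, smooth_bins = 9) {
  stopifnot(inherits(recording, "fg_recording"),
            inherits(noise, "fg_noise_stats"))
  x <- recording$samples
  n <- length(x)
  fs <- recording$sampling_rate
  X <- stats::fft(x)
  px <- Mod(X)^2
  # reference periodogram as per-bin power level |F|^2 / n_ref, which for
  # stationary noise is invariant to segment length
  level_ref <- noise$spectrum$power * noise$n_ref
  level_ref <- moving_average(level_ref, smooth_bins)
  freq <- (seq_len(n) - 1) * fs / n
  level <- stats::approx(noise$spectrum$freq, level_ref, xout = freq,
                         rule = 2)$y
  noise_power <- level * n          # expected |X|^2 of noise at length n
  gain <- pmin(1, pmax(0, 1 - noise_power / pmax(px, .Machine$double.eps)))
  # enforce conjugate symmetry so the output is real
  if (n > 2) {
    i <- 2:n
    gain[i] <- (gain[i] + gain[n - i + 2]) / 2
  }
  recording$samples <- Re(stats::fft(gain * X, inverse = TRUE)) / n
  recording
}

#' Extract per-impulse sample windows
#'
#' Slices the recording at each accepted interval into a footstep impulse
#' object, flagging clipped impulses (3 or more consecutive samples at or
#' above 99% of full scale).
#'
#' @param recording An `fg_recording`.
#' @param impulses data.frame of accepted intervals (from
#'   [filter_footstep_impulses()]); must lie within the recording.
#' @param full_scale Full-scale amplitude used for the clipping flag.
#' @return List of `fg_impulse` objects: `samples`, `onset_time`,
#'   `offset_time`, `sampling_rate`, `sensor_id`, `index_in_trace`,
#'   `clipped`.
#' @export
segment_footsteps <- function(recording, impulses, full_scale = 1) {
  stopifnot(inherits(recording, "fg_recording"), is.data.frame(impulses))
  fs <- recording$sampling_rate
  n <- length(recording$samples)
  lapply(seq_len(nrow(impulses)), function(i) {
    i0 <- base::floor(impulses$onset[i] * fs) + 1
    i1 <- ceiling(impulses$offset[i] * fs)
    if (i0 < 1 || i1 > n || i1 <= i0) stop("impulse interval out of bounds")
    s <- recording$samples[i0:i1]
    structure(
      list(samples = s, onset_time = impulses$onset[i],
           offset_time = impulses$offset[i], sampling_rate = fs,
           sensor_id = recording$sensor_id,
           index_in_trace = impulses$index_in_trace[i] %||% i,
           clipped = is_clipped(s, full_scale)),
      class = "fg_impulse")
  })
}

#' Rebalance per-subject sample counts
#'
#' Equalizes every subject's sample count to the cohort median (midpoint
#' convention for even cohorts, rounded to the nearest integer): subjects
#' below the median are bootstrapped (drawn with replacement), subjects
#' above it are down-sampled without replacement, subjects at the median
#' are kept as-is.
#'
#' @param sample_lists Named or unnamed list; one list/vector of samples per
#'   subject.
#' @param seed Optional integer seed.
#' @return List of the same shape with equalized counts.
#' @export
rebalance_subjects <- function(sample_lists, seed = NULL) {
  stopifnot(is.list(sample_lists), length(sample_lists) >= 1)
  counts <- vapply(sample_lists, length, integer(1))
  target <- as.integer(round(stats::median(counts)))
  with_seed_if(seed, {
    lapply(sample_lists, function(s) {
      n <- length(s)
      if (n == target) s
      else if (n < target) s[sample.int(n, target, replace = TRUE)]
      else s[sort(sample.int(n, target, replace = FALSE))]
    })
  })
}
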