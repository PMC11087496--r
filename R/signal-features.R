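# Implicit signal-based features of footstep impulses and traces.

impulse_samples <- function(impulse) {
  if (inherits(impulse, "fg_impulse")) impulse$samples else as.numeric(impulse)
}

#' Basic time-domain statistics of an impulse
#'
#' Mean, sample (n-1) standard deviation, skewness and kurtosis of the
#' impulse samples. Skewness and kurtosis are standardized by the
#' population moments; kurtosis is reported raw (a Normal signal gives 3,
#' not 0). A constant signal returns `(c, 0, 0, 0)` by convention.
#'
#' @param impulse An `fg_impulse` or numeric vector with at least 4 samples.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
basic_stats <- function(impulse) {
  x <- impulse_samples(impulse)
  if (length(x) < 4) stop("need at least 4 samples")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  z <- (x - m) / sd_pop(x)
  c(mean = m, sd = s, skewness = mean(z^3), kurtosis = mean(z^4))
}

#' Dominant frequency at foot strike or foot off
#'
#' Frequency of maximal periodogram power within 0-`fmax` Hz, computed on
#' the strike segment (first 40% of the impulse) or the off segment (last
#' 40%). The strike frequency reflects the contact surface and frictional
#' forces; the off frequency reflects ankle push-off power.
#'
#' @param impulse An `fg_impulse`, or a numeric vector with `sampling_rate`.
#' @param phase `"strike"` or `"off"`.
#' @param sampling_rate Required when `impulse` is a bare vector.
#' @param fmax Upper frequency bound in Hz.
#' @return Dominant frequency in Hz (0 for a DC-only segment).
#' @export
dominant_frequency <- function(impulse, phase = c("strike", "off"),
                               sampling_rate = NULL, fmax = 250) {
  phase <- match.arg(phase)
  x <- impulse_samples(impulse)
  fs <- if (inherits(impulse, "fg_impulse")) impulse$sampling_rate
        else sampling_rate
  if (is.null(fs)) stop("sampling_rate required for bare sample vectors")
  n <- length(x)
  k <- ceiling(0.4 * n)
  seg <- if (phase == "strike") x[seq_len(k)] else x[seq(n - k + 1, n)]
  p <- Mod(stats::fft(seg))^2
  freq <- (seq_along(seg) - 1) * fs / length(seg)
  sel <- freq <= min(fmax, fs / 2)
  freq[sel][which.max(p[sel])]
}

#' Footstep signal energy
#'
#' Sum of squared samples; with footsteps denoised beforehand, a stronger
#' footstep force maps to a larger energy.
#'
#' @param impulse An `fg_impulse` or numeric vector.
#' @return Non-negative energy (volts squared times samples).
#' @export
footstep_energy <- function(impulse) {
  x <- impulse_samples(impulse)
  sum(x^2)
}

#' Energy variability across the footsteps of a trace
#'
#' Coefficient of variation (population SD / mean) of per-footstep
#' energies: 0 iff all energies are equal, invariant to a common energy
#' scaling.
#'
#' @param energies Numeric vector of at least 2 per-footstep energies.
#' @return Non-negative dimensionless variability.
#' @export
energy_variability <- function(energies) {
  stopifnot(is.numeric(energies), length(energies) >= 2)
  m <- mean(energies)
  if (m == 0) stop("zero mean energy; variability undefined")
  sd_pop(energies) / m
}

#' Clipping detector
#'
#' An impulse counts as clipped when at least 3 consecutive samples sit at
#' or above 99% of full scale in absolute value (a saturated plateau), not
#' when a single sample touches full scale.
#'
#' @param impulse An `fg_impulse` or numeric vector.
#' @param full_scale Full-scale amplitude (> 0).
#' @return Logical flag.
#' @export
is_clipped <- function(impulse, full_scale = 1) {
  stopifnot(full_scale > 0)
  x <- impulse_samples(impulse)
  sat <- abs(x) >= 0.99 * full_scale
  if (!any(sat)) return(FALSE)
  r <- rle(sat)
  any(r$values & r$lengths >= 3)
}

clipping_extent <- function(impulse, full_scale = 1) {
  sum(abs(impulse_samples(impulse)) >= 0.99 * full_scale)
}

#' Most representative footstep of a trace
#'
#' The unclipped footstep with the highest energy; if every footstep is
#' clipped, the one with the smallest clipping extent (ties broken by
#' energy). Its spectrum summarizes the trace at full resolution.
#'
#' @param impulses Non-empty list of `fg_impulse` objects.
#' @param full_scale Full-scale amplitude for the clipping decision when
#'   impulses carry no `clipped` flag.
#' @return The selected `fg_impulse`.
#' @export
representative_footstep <- function(impulses, full_scale = 1) {
  if (length(impulses) == 0) stop("empty footstep list")
  energies <- vapply(impulses, footstep_energy, numeric(1))
  clipped <- vapply(impulses, function(im) {
    if (inherits(im, "fg_impulse") && !is.null(im$clipped)) im$clipped
    else is_clipped(im, full_scale)
  }, logical(1))
  if (any(!clipped)) {
    cand <- which(!clipped)
    impulses[[cand[which.max(energies[cand])]]]
  } else {
    ext <- vapply(impulses, clipping_extent, numeric(1),
                  full_scale = full_scale)
    cand <- which(ext == min(ext))
    impulses[[cand[which.max(energies[cand])]]]
  }
}

#' Band-power summary of an impulse spectrum
#'
#' Unit-sum power in `n_bands` log-spaced bands over `[1, fmax]` Hz; the
#' compact spectral shape descriptor used at the step level.
#'
#' @param impulse An `fg_impulse`, or numeric vector with `sampling_rate`.
#' @param n_bands Number of log-spaced bands.
#' @param sampling_rate Required for bare vectors.
#' @param fmax Upper frequency bound in Hz.
#' @return Numeric vector of band powers summing to 1 (uniform when the
#'   segment has no power in band).
#' @export
psd_band_powers <- function(impulse, n_bands = 3, sampling_rate = NULL,
                            fmax = 250) {
  x <- impulse_samples(impulse)
  fs <- if (inherits(impulse, "fg_impulse")) impulse$sampling_rate
        else sampling_rate
  if (is.null(fs)) stop("sampling_rate required for bare sample vectors")
  p <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_along(x) - 1) * fs / length(x)
  edges <- exp(seq(log(1), log(min(fmax, fs / 2)), length.out = n_bands + 1))
  pow <- vapply(seq_len(n_bands), function(b) {
    sel <- freq >= edges[b] & freq < edges[b + 1]
    sum(p[sel])
  }, numeric(1))
  tot <- sum(pow)
  if (tot == 0) rep(1 / n_bands, n_bands) else pow / tot
}
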