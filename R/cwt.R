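# Continuous wavelet transform with generalized Morse wavelets, used to
# isolate the floor-resonance band before strike picking.

# Frequency-domain Morse wavelet, evaluated on angular frequencies `w`
# (rad/sample) for a wavelet whose peak response sits at `w_peak`.
# Analytic: zero response at non-positive frequencies.
morse_filter <- function(w, w_peak, beta, gamma) {
  wp <- (beta / gamma)^(1 / gamma)      # peak of w^beta exp(-w^gamma)
  s <- wp / w_peak                      # scale mapping peak -> w_peak
  h <- numeric(length(w))
  pos <- w > 0
  lw <- beta * log(s * w[pos]) - (s * w[pos])^gamma
  lpk <- beta * log(wp) - wp^gamma
  h[pos] <- 2 * exp(lw - lpk)           # peak response normalized to 2
  h
}

#' Floor-band wavelet envelope
#'
#' Continuous wavelet transform of the recording with generalized Morse
#' wavelets (symmetric family, `gamma = 3`), restricted to the band where
#' the floor's natural frequency lies. The envelope is the mean wavelet
#' coefficient magnitude across the band's scales, lightly smoothed in
#' time; it is non-negative everywhere, tracks footstep-impulse energy in
#' the floor-resonance band, and suppresses out-of-band noise such as
#' mechanical device disturbances.
#'
#' @param recording An [sensor_recording()] (or numeric vector with
#'   `sampling_rate`).
#' @param band Frequency band in Hz, default the 5-25 Hz floor-resonance
#'   band; must be non-empty and below Nyquist.
#' @param gamma,beta Morse shape parameters. `beta = 8` keeps the wavelet
#'   short enough to resolve strikes about 0.05 s apart in time at these
#'   frequencies.
#' @param voices Number of log-spaced scales across the band.
#' @param smooth Width (s) of the moving-average smoothing of the envelope;
#'   0 disables it.
#' @param sampling_rate Required when `recording` is a bare vector.
#' @return Object of class `fg_envelope`: `values` (non-negative numeric)
#'   and `sampling_rate`.
#' @export
wavelet_band_envelope <- function(recording, band = c(5, 25), gamma = 3,
                                  beta = 8, voices = 12, smooth = 0.1,
                                  sampling_rate = NULL) {
  if (inherits(recording, "fg_recording")) {
    x <- recording$samples
    fs <- recording$sampling_rate
  } else {
    x <- as.numeric(recording)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for bare sample vectors")
  }
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stop("band must be a non-empty interval inside (0, Nyquist)")
  }
  n <- length(x)
  n2 <- next_pow2(n)
  X <- stats::fft(c(x, numeric(n2 - n)))
  w <- 2 * pi * (seq_len(n2) - 1) / n2          # rad/sample, [0, 2*pi)
  w[w >= pi] <- 0                               # kill negative-frequency half
  centers <- exp(seq(log(band[1]), log(band[2]), length.out = voices))
  acc <- numeric(n2)
  for (fc in centers) {
    h <- morse_filter(w, w_peak = 2 * pi * fc / fs, beta = beta,
                      gamma = gamma)
    acc <- acc + Mod(stats::fft(X * h, inverse = TRUE) / n2)
  }
  env <- acc[seq_len(n)] / voices
  if (smooth > 0) env <- pmax(moving_average(env, round(smooth * fs)), 0)
  structure(list(values = env, sampling_rate = fs), class = "fg_envelope")
}

#' @export
print.fg_envelope <- function(x, ...) {
  cat(sprintf("<fg_envelope> %d samples @ %g Hz, max %.3g\n",
              length(x$values), x$sampling_rate, max(x$values)))
  invisible(x)
}
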