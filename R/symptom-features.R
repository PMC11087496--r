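# Symptom-based gait features: strike times, step time, cadence,
# variability, left-right symmetry, and initial-contact classification.

#' Pick foot strikes from a band envelope
#'
#' Local maxima of the floor-band envelope with height at least
#' `prominence_factor` times the median envelope and pairwise separation of
#' at least `min_separation` (larger peaks win). Each kept peak is then
#' refined to a strike time: by default the amplitude-weighted centroid of
#' the envelope mass around the peak, which is robust to envelope noise so
#' step-time differences stay stable at low SNR; alternatively a backward
#' search for the envelope onset (approximating the initial-contact time),
#' or the raw peak position.
#'
#' @param envelope An [wavelet_band_envelope()] result.
#' @param min_separation Minimum strike separation in s. The default 0.25 s
#'   resolves cadences beyond 200 steps/min.
#' @param prominence_factor Height threshold as a multiple of the median
#'   envelope.
#' @param refine `"centroid"` (default), `"onset"` (last crossing of
#'   `onset_fraction` times the peak height before the peak), or `"peak"`.
#' @param onset_fraction Envelope fraction defining the onset crossing
#'   (leading-edge half-maximum by default).
#' @return Strictly increasing numeric vector of strike times in s
#'   (empty for a flat envelope).
#' @export
detect_foot_strikes <- function(envelope, min_separation = 0.25,
                                prominence_factor = 2,
                                refine = c("centroid", "onset", "peak"),
                                onset_fraction = 0.5) {
  refine <- match.arg(refine)
  stopifnot(inherits(envelope, "fg_envelope"))
  v <- envelope$values
  if (any(v < 0)) stop("envelope must be non-negative")
  fs <- envelope$sampling_rate
  n <- length(v)
  if (n < 3) return(numeric(0))
  thr <- prominence_factor * stats::median(v)
  core <- 2:(n - 1)
  is_peak <- v[core] > v[core - 1] & v[core] >= v[core + 1] &
    v[core] > thr & v[core] > 0
  peaks <- core[is_peak]
  if (length(peaks) == 0) return(numeric(0))
  # greedy non-maximum suppression: tallest first
  peaks <- peaks[order(v[peaks], decreasing = TRUE)]
  min_gap <- round(min_separation * fs)
  kept <- integer(0)
  for (p in peaks) {
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  times <- switch(refine,
    peak = as.numeric(kept),
    onset = vapply(seq_along(kept), function(i) {
      p <- kept[i]
      lower <- if (i > 1) kept[i - 1] else 1
      j <- p
      while (j > lower && v[j] > onset_fraction * v[p]) j <- j - 1
      as.numeric(j)
    }, numeric(1)),
    centroid = vapply(seq_along(kept), function(i) {
      p <- kept[i]
      half <- round(0.6 * min_gap)
      lo <- max(1, p - half)
      hi <- min(n, p + half)
      # contiguous half-height region around the peak, capped by the
      # window, so neighboring strikes do not drag the centroid
      j0 <- p
      while (j0 > lo && v[j0 - 1] >= 0.5 * v[p]) j0 <- j0 - 1
      j1 <- p
      while (j1 < hi && v[j1 + 1] >= 0.5 * v[p]) j1 <- j1 + 1
      idx <- j0:j1
      w <- v[idx] - 0.5 * v[p]
      if (sum(w) <= 0) as.numeric(p) else sum(idx * w) / sum(w)
    }, numeric(1)))
  sort(unique((times - 1) / fs))
}

#' Step times from a strike sequence
#'
#' Differences between consecutive foot strike times; the interval between
#' one leg's contact and the contralateral contact.
#'
#' @param strikes Strictly increasing numeric vector of strike times in s.
#' @return Numeric vector of `N - 1` positive step times (empty for fewer
#'   than 2 strikes).
#' @export
step_times <- function(strikes) {
  stopifnot(is.numeric(strikes), !is.unsorted(strikes, strictly = TRUE))
  if (length(strikes) < 2) return(numeric(0))
  diff(strikes)
}

#' Cadence from a strike sequence
#'
#' `(N - 1) / (t_N - t_1)` strikes per second, reported in steps/min.
#'
#' @param strikes Strictly increasing numeric vector of at least 2 strike
#'   times in s.
#' @return Cadence in steps per minute.
#' @export
cadence <- function(strikes) {
  stopifnot(is.numeric(strikes), !is.unsorted(strikes, strictly = TRUE))
  n <- length(strikes)
  if (n < 2) stop("cadence requires at least 2 strikes")
  (n - 1) / (strikes[n] - strikes[1]) * 60
}

#' Step-time variability
#'
#' Sample (n-1) standard deviation of the step times within a walking
#' trace; a balance-related symptom measure.
#'
#' @param step_time_series Numeric vector of at least 2 step times (s).
#' @return Standard deviation in s.
#' @export
step_time_variability <- function(step_time_series) {
  if (length(step_time_series) < 2) {
    stop("step-time variability requires at least 2 step times")
  }
  stats::sd(step_time_series)
}

#' 90th-percentile amplitude of a footstep
#'
#' The per-footstep amplitude summary entering the symmetry score: the 90th
#' percentile of the absolute sample values, less clipping-sensitive than
#' the maximum.
#'
#' @param impulse An `fg_impulse` or numeric vector.
#' @return Non-negative amplitude.
#' @export
x90_amplitude <- function(impulse) {
  as.numeric(stats::quantile(abs(impulse_samples(impulse)), 0.9, names = FALSE))
}

#' Left-right symmetry score
#'
#' `1 - mean_i |X90[i+1] - X90[i]| / (0.5 (X90[i+1] + X90[i]))` over the
#' `N - 1` adjacent footstep pairs of a trace: 1 for perfectly consistent
#' adjacent amplitudes, lower as alternating left-right amplitude
#' differences grow. The score can be negative for extreme asymmetry
#' (infimum -1) and is reported unclamped; it is invariant to a global
#' amplitude scaling.
#'
#' @param x90 Numeric vector of per-footstep 90th-percentile amplitudes
#'   (length >= 2, non-negative, no adjacent pair summing to zero).
#' @return Symmetry score in `(-1, 1]`.
#' @export
symmetry_score <- function(x90) {
  stopifnot(is.numeric(x90), length(x90) >= 2, all(x90 >= 0))
  a <- x90[-length(x90)]
  b <- x90[-1]
  denom <- 0.5 * (a + b)
  if (any(denom == 0)) stop("adjacent footstep pair with zero amplitude")
  1 - mean(abs(b - a) / denom)
}

#' Normalized footstep spectrum
#'
#' Power spectrum of a segmented footstep over 0-`fmax` Hz, aggregated into
#' `n_bins` equal-width frequency bins and normalized to unit total power
#' (invariant to amplitude scaling); the input representation of the
#' initial-contact classifier.
#'
#' @param impulse An `fg_impulse`, or numeric vector with `sampling_rate`.
#' @param n_bins Number of output bins.
#' @param sampling_rate Required for bare vectors.
#' @param fmax Upper frequency bound in Hz.
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
footstep_spectrum <- function(impulse, n_bins = 40, sampling_rate = NULL,
                              fmax = 250) {
  x <- impulse_samples(impulse)
  if (length(x) == 0) stop("empty impulse")
  fs <- if (inherits(impulse, "fg_impulse")) impulse$sampling_rate
        else sampling_rate
  if (is.null(fs)) stop("sampling_rate required for bare sample vectors")
  p <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_along(x) - 1) * fs / length(x)
  top <- min(fmax, fs / 2)
  bin <- base::floor(freq / top * n_bins) + 1
  sel <- freq <= top & bin <= n_bins
  pow <- vapply(seq_len(n_bins), function(b) sum(p[sel][bin[sel] == b]),
                numeric(1))
  tot <- sum(pow)
  if (tot == 0) stop("impulse has no spectral power")
  pow / tot
}

#' Train the initial-contact classifier
#'
#' Support vector machine with a quadratic (degree-2 polynomial) kernel
#' over normalized footstep spectra, capturing interactions between
#' frequency ranges. Decision margins are calibrated to class probabilities
#' by Platt-style logistic fits (one-vs-one, renormalized to a simplex), as
#' provided by the underlying SVM implementation.
#'
#' @param spectra Numeric matrix, one normalized spectrum per row.
#' @param labels Contact labels in `c("heel", "midfoot", "toe")`, at least
#'   2 classes with at least 5 examples each.
#' @param cost SVM cost parameter.
#' @param seed Optional integer seed (probability calibration resamples).
#' @return Object of class `fg_contact_model`.
#' @export
train_contact_classifier <- function(spectra, labels, cost = 10,
                                     seed = NULL) {
  spectra <- as.matrix(spectra)
  labels <- as.character(labels)
  stopifnot(nrow(spectra) == length(labels),
            all(labels %in% c("heel", "midfoot", "toe")))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 contact classes")
  if (any(tab < 5)) stop("need at least 5 examples per class")
  y <- factor(labels, levels = intersect(c("heel", "midfoot", "toe"),
                                         unique(labels)))
  fit <- with_seed_if(seed %||% 1L, {
    e1071::svm(spectra, y, kernel = "polynomial", degree = 2, coef0 = 1,
               cost = cost, probability = TRUE, scale = FALSE)
  })
  structure(list(fit = fit, classes = levels(y), n_bins = ncol(spectra)),
            class = "fg_contact_model")
}

#' Contact-class probabilities for footstep spectra
#'
#' @param model An [train_contact_classifier()] result.
#' @param spectra Numeric vector (one spectrum) or matrix (one per row)
#'   with the model's bin count.
#' @return Matrix of class probabilities (rows sum to 1), columns in the
#'   model's class order.
#' @export
predict_contact_probs <- function(model, spectra) {
  stopifnot(inherits(model, "fg_contact_model"))
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  if (ncol(spectra) != model$n_bins) {
    stop("spectrum bin count does not match the trained model")
  }
  pred <- stats::predict(model$fit, spectra, probability = TRUE)
  pr <- attr(pred, "probabilities")
  pr[, model$classes, drop = FALSE]
}

#' Probability of toe initial contact
#'
#' The calibrated probability that a footstep spectrum reflects a toe
#' initial contact, the progression-relevant contact symptom.
#'
#' @param model An [train_contact_classifier()] result trained with a toe
#'   class.
#' @param spectrum Numeric vector: one normalized spectrum.
#' @return Probability in `[0, 1]`.
#' @export
toe_contact_probability <- function(model, spectrum) {
  stopifnot(inherits(model, "fg_contact_model"))
  if (!"toe" %in% model$classes) {
    stop("model was trained without a toe class")
  }
  pr <- predict_contact_probs(model, spectrum)
  as.numeric(pr[, "toe"])
}
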