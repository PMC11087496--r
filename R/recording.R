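# Container for a single sensor's voltage time series.

#' Sensor recording
#'
#' One geophone channel: a voltage time series with its sampling rate, a
#' sensor id, and the index interval of a pure-noise reference segment used
#' for threshold estimation and spectral denoising.
#'
#' @param samples Numeric vector of voltages.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param sensor_id Integer sensor identifier.
#' @param noise_reference Length-2 integer vector `c(first, last)` indexing a
#'   non-empty pure-noise stretch of `samples`.
#' @param position Sensor position along the walkway in meters (optional,
#'   carried for provenance).
#' @return An object of class `fg_recording`.
#' @export
sensor_recording <- function(samples, sampling_rate, sensor_id = 1L,
                             noise_reference = NULL, position = NA_real_) {
  stopifnot(is.numeric(samples), is.numeric(sampling_rate), sampling_rate > 0)
  if (is.null(noise_reference)) {
    noise_reference <- c(1L, max(1L, min(length(samples),
                                         as.integer(sampling_rate))))
  }
  noise_reference <- as.integer(noise_reference)
  if (length(noise_reference) != 2 ||
      noise_reference[1] < 1 || noise_reference[2] < noise_reference[1] ||
      noise_reference[2] > length(samples)) {
    stop("noise_reference must be a valid, non-empty index interval")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         sensor_id = as.integer(sensor_id), noise_reference = noise_reference,
         position = position),
    class = "fg_recording"
  )
}

#' @export
print.fg_recording <- function(x, ...) {
  cat(sprintf("<fg_recording> sensor %d: %d samples @ %g Hz (%.2f s)\n",
              x$sensor_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

# Duration in seconds.
recording_duration <- function(recording) {
  length(recording$samples) / recording$sampling_rate
}
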