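# Normative functional scale for muscular dystrophy based on the 100-m run.

#' Subject biometrics
#'
#' Bundles the person-level covariates used both by the normative 100-m
#' performance model and by the person level of the hierarchical stage
#' predictor.
#'
#' @param age Age in years (> 0).
#' @param weight Body mass in kg (> 0).
#' @param height Standing height in m (> 0).
#' @param gender `"male"` or `"female"`.
#' @return An object of class `fg_biometrics`: a list with fields `age`,
#'   `weight`, `height`, `gender` and the derived `bmi` (kg/m^2).
#' @export
biometrics <- function(age, weight, height, gender = c("male", "female")) {
  gender <- match.arg(gender)
  stopifnot(is.numeric(age), age > 0, is.numeric(weight), weight > 0,
            is.numeric(height), height > 0)
  structure(
    list(age = age, weight = weight, height = height, gender = gender,
         bmi = weight / height^2),
    class = "fg_biometrics"
  )
}

#' Normative 100-m run performance
#'
#' Expresses an individual's 100-m run time as a percentage of the running
#' speed predicted for a healthy 50th-percentile reference of the same age
#' and body-mass index. The numerator is the regression-based reference
#' speed `36.72 - 1.51 * age + 0.26 * weight / height^2`; the ratio of this
#' reference to the actual run time, times 100, is the normative percent.
#' 100% means the individual runs at the reference speed of their age group;
#' lower values indicate functional decline.
#'
#' @param bio An [biometrics()] object.
#' @param actual_100m_time Measured 100-m run time in seconds (> 0).
#' @return Predicted 100-m performance in percent.
#' @export
predicted_100m_percent <- function(bio, actual_100m_time) {
  stopifnot(inherits(bio, "fg_biometrics"))
  if (!is.numeric(actual_100m_time) || actual_100m_time <= 0) {
    stop("actual_100m_time must be a positive number of seconds")
  }
  numerator <- 36.72 - 1.51 * bio$age + 0.26 * bio$weight / bio$height^2
  if (numerator <= 0) {
    stop("reference speed is non-positive for these biometrics; ",
         "the normative model does not apply")
  }
  numerator / actual_100m_time * 100
}

#' Discretize normative 100-m percent into functional stages
#'
#' Maps the continuous normative percent onto the 8-level functional
#' progression scale (stage 0 = faster than the healthy reference median,
#' stage 7 = likely to lose ambulation). The printed integer ranges of the
#' scale (e.g. stage 1 spans 80-99%) are applied as half-open intervals
#' `[lower, upper)` whose lower edges are the printed lower bounds; a
#' percent of 100 or more maps to stage 0.
#'
#' @param percent Numeric vector of normative 100-m percents (>= 0).
#' @return Integer vector of stages in `0:7`.
#' @export
stage_from_percent <- function(percent) {
  if (!is.numeric(percent) || any(!is.finite(percent)) || any(percent < 0)) {
    stop("percent must be finite and non-negative")
  }
  # findInterval over the lower edges 20,30,40,50,60,80,100 counts how many
  # boundaries the percent has reached; stages run opposite to percent.
  edges <- c(20, 30, 40, 50, 60, 80, 100)
  as.integer(7L - findInterval(percent, edges))
}

#' Functional stage for a subject
#'
#' Convenience wrapper chaining [predicted_100m_percent()] and
#' [stage_from_percent()].
#'
#' @inheritParams predicted_100m_percent
#' @return A list with `percent` and `stage`.
#' @export
functional_stage <- function(bio, actual_100m_time) {
  pct <- predicted_100m_percent(bio, actual_100m_time)
  list(percent = pct, stage = stage_from_percent(pct))
}
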