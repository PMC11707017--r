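#' Conventions used throughout the package
#'
#' All clinically meaningful constants live in this one object so that no
#' threshold is ever inlined at a call site.  Values follow the
#' international consensus conventions for CGM reporting:
#'
#' * `sensor_range`: CGM sensors report a bounded range; readings outside
#'   \[39, 401\] mg/dL are clamped on ingestion.
#' * `gmi_intercept`, `gmi_slope`: the Glucose Management Indicator maps
#'   mean CGM glucose (mg/dL) onto the HbA1c percentage scale as
#'   `GMI = 3.31 + 0.02392 * mean`.
#' * Range boundaries: in-range is 70–180 mg/dL inclusive; above-range is
#'   `> 180` (cumulative) with level 2 `> 250`; below-range is `< 70`
#'   with level 2 `< 54`.  The banded "level 1" hyperglycemia band is
#'   181–250 mg/dL.
#' * Episode conventions: an event requires at least 15 min beyond
#'   threshold; "prolonged" means sustained at least 120 min; an episode
#'   ends after at least 15 min back in range; gaps longer than 30 min
#'   censor an open episode.
#' * `nocturnal_window`: hours \[0, 6) count as overnight.
#' * `high_cv`: coefficient of variation above 36% flags unstable control.
#'
#' @format A named list.
#' @export
agp_conventions <- list(
  sensor_range       = c(39, 401),
  gmi_intercept      = 3.31,
  gmi_slope          = 0.02392,
  range_low          = 70,
  range_high         = 180,
  level2_hyper       = 250,
  level2_hypo        = 54,
  episode_min        = 15,
  episode_prolonged  = 120,
  episode_recovery   = 15,
  episode_max_gap    = 30,
  nocturnal_window   = c(0, 6),
  near_miss_band     = c(70, 80),
  high_cv            = 36
)

#' Convert a mean glucose to GMI, and back
#'
#' The Glucose Management Indicator is the standard linear mapping of mean
#' CGM glucose onto the HbA1c percentage scale.
#'
#' @param mean_glucose mean glucose in mg/dL, within the sensor range.
#' @param gmi GMI in percent.
#' @return `gmi_from_mean()` returns the GMI in percent;
#'   `mean_from_gmi()` inverts the mapping.
#' @export
gmi_from_mean <- function(mean_glucose) {
  stopifnot(is.numeric(mean_glucose), all(is.finite(mean_glucose)))
  rng <- agp_conventions$sensor_range
  if (any(mean_glucose < rng[1] | mean_glucose > rng[2])) {
    stop("mean glucose outside the sensor range [", rng[1], ", ", rng[2], "]")
  }
  agp_conventions$gmi_intercept + agp_conventions$gmi_slope * mean_glucose
}

#' @rdname gmi_from_mean
#' @export
mean_from_gmi <- function(gmi) {
  stopifnot(is.numeric(gmi), all(is.finite(gmi)))
  (gmi - agp_conventions$gmi_intercept) / agp_conventions$gmi_slope
}
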