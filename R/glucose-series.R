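#' Construct a glucose series
#'
#' The canonical in-memory representation of a CGM trace: a data.frame
#' with a `time` column (POSIXct, strictly increasing, no duplicates) and
#' a `gl` column (glucose in mg/dL, within the sensor reporting range),
#' carrying the nominal sampling interval in minutes as an attribute.
#' Timestamps are naive local times; they are stored in UTC internally so
#' no daylight-saving arithmetic ever applies.
#'
#' @param time POSIXct vector (or something coercible via
#'   [as.POSIXct()] with `tz = "UTC"`).
#' @param gl numeric glucose values in mg/dL, one per timestamp.
#' @param interval nominal sampling interval in minutes (default 5).
#' @return An object of class `glucose_series` (a data.frame).
#' @export
glucose_series <- function(time = as.POSIXct(character(), tz = "UTC"),
                           gl = numeric(), interval = 5) {
  if (!inherits(time, "POSIXct")) {
    time <- as.POSIXct(time, tz = "UTC")
  } else {
    attr(time, "tzone") <- "UTC"
  }
  stopifnot(length(time) == length(gl), is.numeric(gl), interval > 0)
  if (anyNA(time)) stop("unparsable timestamps")
  if (anyNA(gl) || any(!is.finite(gl))) stop("non-finite glucose values")
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps must be strictly increasing with no duplicates")
  }
  rng <- agp_conventions$sensor_range
  if (any(gl < rng[1] | gl > rng[2])) {
    stop("glucose values outside the sensor range [", rng[1], ", ", rng[2],
         "] mg/dL; use clamp_glucose() on raw values first")
  }
  out <- data.frame(time = time, gl = as.numeric(gl))
  attr(out, "interval") <- interval
  class(out) <- c("glucose_series", "data.frame")
  out
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> %d readings, nominal interval %g min\n",
              nrow(x), series_interval(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  %s .. %s  glucose %g-%g mg/dL\n",
                format(x$time[1]), format(x$time[nrow(x)]),
                min(x$gl), max(x$gl)))
    g <- series_gaps(x)
    if (nrow(g) > 0) cat(sprintf("  %d gap(s), longest %g min\n",
                                 nrow(g), max(g$minutes)))
  }
  invisible(x)
}

#' Nominal sampling interval of a glucose series
#' @param series a `glucose_series`.
#' @return interval in minutes.
#' @export
series_interval <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  attr(series, "interval")
}

#' Gaps in a glucose series
#'
#' A gap is any step between consecutive readings longer than the nominal
#' interval.  Gaps are never imputed anywhere in the package; they
#' propagate to the metrics (reading-count denominators) and censor
#' episode detection.
#'
#' @param series a `glucose_series`.
#' @return data.frame with columns `start`, `end` (the readings flanking
#'   the gap) and `minutes` (elapsed time between them).
#' @export
series_gaps <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  if (nrow(series) < 2) {
    return(data.frame(start = series$time[0], end = series$time[0],
                      minutes = numeric()))
  }
  dt <- diff(as.numeric(series$time)) / 60
  idx <- which(dt > series_interval(series) + 1e-9)
  data.frame(start = series$time[idx], end = series$time[idx + 1],
             minutes = dt[idx])
}

#' Clamp raw glucose values to the sensor reporting range
#'
#' @param gl numeric vector of raw glucose values.
#' @param warn emit a warning when any value is clamped (default TRUE).
#' @return clamped values.
#' @export
clamp_glucose <- function(gl, warn = TRUE) {
  rng <- agp_conventions$sensor_range
  n_out <- sum(gl < rng[1] | gl > rng[2], na.rm = TRUE)
  if (warn && n_out > 0) {
    warning(sprintf("%d reading(s) outside [%g, %g] mg/dL clamped",
                    n_out, rng[1], rng[2]))
  }
  pmin(pmax(gl, rng[1]), rng[2])
}
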