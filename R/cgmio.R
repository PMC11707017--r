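#' Read a CGM CSV file
#'
#' Accepts the package's declared dialect only: a header row
#' `timestamp,glucose`, ISO-8601 naive local timestamps
#' (`YYYY-MM-DD HH:MM:SS`, a `T` separator is tolerated), glucose in
#' mg/dL.  Rows are sorted by time; values outside the sensor reporting
#' range are clamped with a warning; duplicate timestamps are rejected.
#'
#' @param path path to the CSV file.
#' @param interval nominal sampling interval in minutes (default 5).
#' @return a [glucose_series()].
#' @export
read_cgm_csv <- function(path, interval = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(tolower(names(df)), c("timestamp", "glucose"))) {
    stop("malformed header: expected `timestamp,glucose`, got `",
         paste(names(df), collapse = ","), "`")
  }
  raw <- sub("T", " ", df$timestamp)
  tm <- as.POSIXct(strptime(raw, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  na <- is.na(tm)
  if (any(na)) {
    tm[na] <- as.POSIXct(strptime(raw[na], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  if (anyNA(tm)) {
    stop("unparsable timestamp(s), first at row ", which(is.na(tm))[1])
  }
  ord <- order(tm)
  tm <- tm[ord]
  gl <- df$glucose[ord]
  if (anyDuplicated(as.numeric(tm))) {
    stop("duplicate timestamps after sorting; refusing to guess")
  }
  glucose_series(tm, clamp_glucose(gl), interval = interval)
}

#' Write a glucose series to CSV
#'
#' Inverse of [read_cgm_csv()]: writes the declared dialect
#' (`timestamp,glucose`, seconds precision, glucose to 0.1 mg/dL) so that
#' read(write(s)) reproduces `s` at that precision.
#'
#' @param series a [glucose_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  df <- data.frame(
    timestamp = format(series$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    glucose = sprintf("%.1f", series$gl)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Snap a glucose series onto its nominal time grid
#'
#' Timestamps are snapped to the nearest point of the `interval`-minute
#' grid anchored at midnight of the first reading's date.  Jitter of up
#' to half an interval moves to the nearest grid point (half-interval
#' ties go to the later point); when two readings land on the same slot
#' the first is kept and the second dropped with a warning.  Missing grid
#' points are never filled in: the output is never longer than the input
#' and gaps propagate.
#'
#' @param series a [glucose_series()].
#' @param interval grid spacing in minutes (default: the series' nominal
#'   interval).
#' @return a [glucose_series()] on the grid.
#' @export
regularize <- function(series, interval = series_interval(series)) {
  stopifnot(inherits(series, "glucose_series"), interval > 0)
  if (nrow(series) == 0) {
    return(glucose_series(interval = interval))
  }
  anchor <- as.POSIXct(format(series$time[1], "%Y-%m-%d"), tz = "UTC")
  step <- interval * 60
  k <- floor((as.numeric(series$time) - as.numeric(anchor)) / step + 0.5)
  snapped <- as.numeric(anchor) + k * step
  keep <- !duplicated(snapped)
  if (any(!keep)) {
    warning(sum(!keep), " reading(s) collided on the grid; kept first")
  }
  glucose_series(as.POSIXct(snapped[keep], tz = "UTC",
                            origin = "1970-01-01"),
                 series$gl[keep], interval = interval)
}
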