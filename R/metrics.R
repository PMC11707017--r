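#' Number of days the sensor was active
#'
#' Counts distinct calendar dates carrying at least one reading.
#'
#' @param series a [glucose_series()].
#' @return integer count (0 for an empty series).
#' @export
days_active <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  length(unique(format(series$time, "%Y-%m-%d", tz = "UTC")))
}

#' Percent of expected sensor data captured
#'
#' `100 * observed readings / (expected_days * 1440 / interval)`.
#' Gaps lower the numerator; nothing is imputed.
#'
#' @param series a [glucose_series()].
#' @param expected_days nominal wear period in days (>= 1).
#' @param interval nominal interval in minutes; must divide 1440.
#' @return percentage.
#' @export
percent_captured <- function(series, expected_days = 14,
                             interval = series_interval(series)) {
  stopifnot(inherits(series, "glucose_series"), expected_days >= 1)
  if (1440 %% interval != 0) {
    stop("interval must divide 1440 minutes")
  }
  100 * nrow(series) / (expected_days * 1440 / interval)
}

#' Mean glucose
#'
#' Unweighted arithmetic mean of the readings (each reading counts
#' equally; gap periods are simply absent from the average).
#'
#' @param series a non-empty [glucose_series()].
#' @return mean glucose in mg/dL.
#' @export
mean_glucose <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  if (nrow(series) == 0) stop("mean glucose of an empty series")
  mean(series$gl)
}

#' Glucose coefficient of variation
#'
#' `100 * population SD / mean`.  The population SD (divisor `n`) is
#' used because the series is the entire observation window, not a
#' sample from it.
#'
#' @param series a non-empty [glucose_series()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return CV in percent.
#' @export
cv_glucose <- function(series, sd_type = c("population", "sample")) {
  stopifnot(inherits(series, "glucose_series"))
  sd_type <- match.arg(sd_type)
  if (nrow(series) == 0) stop("CV of an empty series")
  n <- nrow(series)
  s <- stats::sd(series$gl)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (n == 1) s <- 0
  100 * s / mean(series$gl)
}

#' Time in glycemic ranges
#'
#' Reading-count fractions of the observed readings in the standard
#' ranges, under either time-above-range convention:
#'
#' * `cumulative` (the reporting standard): `pct_above_180` counts every
#'   reading `> 180` mg/dL, so
#'   `pct_below_70 + pct_70_180 + pct_above_180 = 100` exactly.
#' * `banded`: `pct_above_180` counts only the level-1 band
#'   181–250 mg/dL (`> 180` and `<= 250`).  Then
#'   `pct_above_180 + pct_above_250` reproduces the cumulative figure
#'   exactly.  This convention is exposed because analyses that read
#'   "level 1" literally produce it in place of the cumulative figure,
#'   a known failure mode worth being able to reproduce.
#'
#' Boundary semantics: `pct_above_250` is strict `> 250`; in-range is
#' inclusive `70 <= g <= 180`; `pct_below_70` is strict `< 70`;
#' `pct_below_54` is strict `< 54`.
#'
#' @param series a non-empty [glucose_series()].
#' @param convention `"cumulative"` (default) or `"banded"`.
#' @return named numeric vector `pct_above_250`, `pct_above_180`,
#'   `pct_70_180`, `pct_below_70`, `pct_below_54`, with the underlying
#'   integer reading counts in attribute `counts` (the banded/cumulative
#'   reconciliation is exact at the count level).
#' @export
time_in_ranges <- function(series,
                           convention = c("cumulative", "banded")) {
  stopifnot(inherits(series, "glucose_series"))
  convention <- match.arg(convention)
  if (nrow(series) == 0) stop("time in ranges of an empty series")
  g <- series$gl
  n <- length(g)
  hi <- agp_conventions$range_high
  lo <- agp_conventions$range_low
  l2 <- agp_conventions$level2_hyper
  above_180 <- if (convention == "cumulative") {
    sum(g > hi)
  } else {
    sum(g > hi & g <= l2)
  }
  counts <- c(n_above_250 = sum(g > l2),
              n_above_180 = above_180,
              n_70_180    = sum(g >= lo & g <= hi),
              n_below_70  = sum(g < lo),
              n_below_54  = sum(g < agp_conventions$level2_hypo))
  structure(100 * counts / n,
            names = c("pct_above_250", "pct_above_180", "pct_70_180",
                      "pct_below_70", "pct_below_54"),
            counts = counts, n = n)
}

#' Full AGP metric report
#'
#' Assembles the ten standard summary metrics: days active, % captured,
#' mean glucose, GMI, CV, and the five time-in-range percentages, with
#' the time-above-range convention recorded.
#'
#' @param series a non-empty [glucose_series()].
#' @param expected_days nominal wear period (default 14).
#' @param convention time-above-range convention (see
#'   [time_in_ranges()]).
#' @return object of class `metric_report`: a named list of the ten
#'   metrics plus `tar_convention`.
#' @export
metric_report <- function(series, expected_days = 14,
                          convention = c("cumulative", "banded")) {
  convention <- match.arg(convention)
  tir <- time_in_ranges(series, convention)
  mg <- mean_glucose(series)
  out <- c(list(days_active = days_active(series),
                pct_captured = percent_captured(series, expected_days),
                mean_glucose = mg,
                gmi = gmi_from_mean(mg),
                cv = cv_glucose(series)),
           as.list(tir),
           list(tar_convention = convention))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> (time-above-range convention:",
      x$tar_convention, ")\n")
  fmt <- function(v) formatC(v, format = "f", digits = 1)
  cat(sprintf("  days active     %d\n", x$days_active))
  cat(sprintf("  %% captured      %s\n", fmt(x$pct_captured)))
  cat(sprintf("  mean glucose    %s mg/dL\n", fmt(x$mean_glucose)))
  cat(sprintf("  GMI             %s %%\n", fmt(x$gmi)))
  cat(sprintf("  CV              %s %%\n", fmt(x$cv)))
  cat(sprintf("  %% >250          %s\n", fmt(x$pct_above_250)))
  cat(sprintf("  %% >180          %s\n", fmt(x$pct_above_180)))
  cat(sprintf("  %% 70-180        %s\n", fmt(x$pct_70_180)))
  cat(sprintf("  %% <70           %s\n", fmt(x$pct_below_70)))
  cat(sprintf("  %% <54           %s\n", fmt(x$pct_below_54)))
  invisible(x)
}
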