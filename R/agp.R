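#' Time-of-day percentile bands (the AGP curve)
#'
#' Pools all readings across days by clock-time bin and computes the
#' 5th/25th/50th/75th/95th percentiles per bin with the
#' linear-interpolation quantile definition ([stats::quantile()]
#' type 7).  Bins with no readings are reported with `NA` percentiles
#' and flagged, never interpolated, so downstream narratives cannot
#' mistake missing data for euglycemia.
#'
#' @param series a non-empty [glucose_series()].
#' @param bin_width bin width in minutes; must divide 1440 (default 60).
#' @return object of class `agp_bands`: a data.frame with one row per
#'   clock bin and columns `bin_start` (minutes after midnight),
#'   `clock` ("HH:MM"), `n`, `p5`, `p25`, `p50`, `p75`, `p95`.
#' @export
compute_bands <- function(series, bin_width = 60) {
  stopifnot(inherits(series, "glucose_series"))
  if (1440 %% bin_width != 0) stop("bin_width must divide 1440")
  if (nrow(series) == 0) stop("AGP bands of an empty series")
  n_bins <- 1440 %/% bin_width
  mod <- as.numeric(series$time) %% 86400 / 60      # minutes after midnight
  bin <- floor(mod / bin_width)
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  out <- data.frame(bin_start = (seq_len(n_bins) - 1) * bin_width)
  out$clock <- sprintf("%02d:%02d", out$bin_start %/% 60,
                       out$bin_start %% 60)
  out$n <- as.integer(tabulate(bin + 1, nbins = n_bins))
  qs <- matrix(NA_real_, n_bins, 5,
               dimnames = list(NULL, c("p5", "p25", "p50", "p75", "p95")))
  for (b in which(out$n > 0)) {
    qs[b, ] <- stats::quantile(series$gl[bin == b - 1], probs,
                               type = 7, names = FALSE)
  }
  out <- cbind(out, qs)
  attr(out, "bin_width") <- bin_width
  attr(out, "quantile_type") <- 7L
  class(out) <- c("agp_bands", "data.frame")
  out
}

#' Interquartile-range profile and its maximal window
#'
#' Per-bin IQR (`p75 - p25`) from AGP bands, plus the clock window where
#' the IQR is highest.  Empty bins are excluded from the search; ties
#' are broken by the earliest clock time so narratives are
#' deterministic.
#'
#' @param bands an [compute_bands()] result.
#' @return data.frame with columns `bin_start`, `clock`, `iqr`;
#'   attributes `max_window` (named vector `start`, `end`, minutes after
#'   midnight) and `max_iqr`.
#' @export
iqr_profile <- function(bands) {
  stopifnot(inherits(bands, "agp_bands"))
  if (all(bands$n == 0)) stop("all AGP bins are empty")
  out <- data.frame(bin_start = bands$bin_start, clock = bands$clock,
                    iqr = bands$p75 - bands$p25)
  occupied <- which(bands$n > 0)
  best <- occupied[which.max(out$iqr[occupied])]   # which.max: first of ties
  bw <- attr(bands, "bin_width")
  attr(out, "max_window") <- c(start = bands$bin_start[best],
                               end = bands$bin_start[best] + bw)
  attr(out, "max_iqr") <- out$iqr[best]
  out
}

#' Plot AGP percentile bands
#'
#' A simple base-graphics rendering of the 5-95 and 25-75 percentile
#' envelopes with the median curve, for quick inspection.  Cosmetic
#' only.
#'
#' @param x an `agp_bands` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agp_bands <- function(x, ...) {
  occ <- x$n > 0
  h <- (x$bin_start + attr(x, "bin_width") / 2) / 60
  graphics::plot(h[occ], x$p50[occ], type = "n",
                 xlab = "hour of day", ylab = "glucose (mg/dL)",
                 ylim = range(x[occ, c("p5", "p95")], 70, 250), ...)
  graphics::polygon(c(h[occ], rev(h[occ])), c(x$p5[occ], rev(x$p95[occ])),
                    col = "grey90", border = NA)
  graphics::polygon(c(h[occ], rev(h[occ])), c(x$p25[occ], rev(x$p75[occ])),
                    col = "grey75", border = NA)
  graphics::lines(h[occ], x$p50[occ], lwd = 2)
  graphics::abline(h = c(70, 180), lty = 2)
  invisible(x)
}
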