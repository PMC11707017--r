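#' Detect out-of-range glucose episodes
#'
#' One-pass scan implementing the consensus event conventions: an
#' episode opens at the first reading beyond `threshold` and must be
#' sustained at least `min_duration` minutes to count; it closes once
#' readings have been back within range for at least `end_recovery`
#' minutes (shorter in-range interludes are absorbed into the same
#' episode); any step between consecutive readings longer than
#' `max_gap` minutes censors the open episode — nothing is inferred
#' across missing data.  Episode duration runs from the first to the
#' last beyond-threshold reading plus one nominal interval.
#'
#' @param series a [glucose_series()], expected regularized.
#' @param threshold mg/dL boundary (strict inequality).
#' @param direction `"below"` (hypoglycemia) or `"above"`
#'   (hyperglycemia).
#' @param min_duration minimum episode duration, minutes (default 15).
#' @param end_recovery in-range minutes required to close an episode
#'   (default 15).
#' @param max_gap gap length that censors an open episode, minutes
#'   (default 30).
#' @return data.frame with columns `start`, `end` (POSIXct), `duration`
#'   (min), `extremum` (mg/dL), `kind`, `level` (1 or 2), `nocturnal`,
#'   `prolonged`; zero rows if no episode.  Episodes are disjoint and
#'   time-ordered.
#' @export
detect_episodes <- function(series, threshold, direction = c("below", "above"),
                            min_duration = agp_conventions$episode_min,
                            end_recovery = agp_conventions$episode_recovery,
                            max_gap = agp_conventions$episode_max_gap) {
  stopifnot(inherits(series, "glucose_series"), threshold > 0)
  direction <- match.arg(direction)
  iv <- series_interval(series)
  empty <- data.frame(start = series$time[0], end = series$time[0],
                      duration = numeric(), extremum = numeric(),
                      kind = character(), level = integer(),
                      nocturnal = logical(), prolonged = logical())
  n <- nrow(series)
  if (n == 0) return(empty)
  out <- if (direction == "below") series$gl < threshold else
    series$gl > threshold
  tmin <- as.numeric(series$time) / 60

  eps <- list()
  first_out <- NA_integer_   # index of first excursion reading of open episode
  last_out <- NA_integer_    # index of latest excursion reading
  close_episode <- function() {
    idx <- first_out:last_out
    g <- series$gl[idx][out[idx]]
    dur <- tmin[last_out] - tmin[first_out] + iv
    ext <- if (direction == "below") min(g) else max(g)
    clock <- tmin[idx] %% 1440
    noct_lo <- agp_conventions$nocturnal_window[1] * 60
    noct_hi <- agp_conventions$nocturnal_window[2] * 60
    data.frame(
      start = series$time[first_out],
      end = series$time[last_out] + iv * 60,
      duration = dur, extremum = ext,
      kind = if (direction == "below") "hypo" else "hyper",
      level = if (direction == "below") {
        if (ext < agp_conventions$level2_hypo) 2L else 1L
      } else {
        if (ext > agp_conventions$level2_hyper) 2L else 1L
      },
      nocturnal = any(clock >= noct_lo & clock < noct_hi),
      prolonged = dur >= agp_conventions$episode_prolonged
    )
  }

  for (i in seq_len(n)) {
    gap_before <- i > 1 && (tmin[i] - tmin[i - 1]) > max_gap
    if (!is.na(first_out)) {
      # in-range coverage since the last excursion reading: the excursion
      # reading covers [t, t+iv), reading i covers up to t_i + iv, so the
      # recovered span is t_i - t_last_out minutes
      recovered <- !gap_before && !out[i] &&
        (tmin[i] - tmin[last_out]) >= end_recovery
      if (gap_before || recovered) {
        eps[[length(eps) + 1]] <- close_episode()
        first_out <- NA_integer_
      }
    }
    if (out[i]) {
      if (is.na(first_out) || gap_before) first_out <- i
      last_out <- i
    }
  }
  if (!is.na(first_out)) eps[[length(eps) + 1]] <- close_episode()
  if (length(eps) == 0) return(empty)
  res <- do.call(rbind, eps)
  res <- res[res$duration >= min_duration, , drop = FALSE]
  rownames(res) <- NULL
  res
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)

new_finding <- function(task, facts, sentences, flags = character()) {
  structure(list(task = task, facts = facts,
                 sentences = sentences, flags = flags),
            class = "agp_finding")
}

#' @export
print.agp_finding <- function(x, ...) {
  cat(sprintf("<agp_finding> task: %s\n", x$task))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  cat(" ", render_narrative(x), "\n")
  invisible(x)
}

#' Render a finding as a short narrative
#'
#' Deterministic template fill: the finding's candidate sentences are
#' ordered by priority and at most six are kept (every finding carries
#' at least two), so the rendered text is always 2-6 sentences and
#' every numeral in it comes from the finding's facts.
#'
#' @param finding an `agp_finding`.
#' @return a single string.
#' @export
render_narrative <- function(finding) {
  stopifnot(inherits(finding, "agp_finding"))
  s <- utils::head(finding$sentences, 6)
  paste(s, collapse = " ")
}

per_day_split <- function(series) {
  split(seq_len(nrow(series)),
        format(series$time, "%Y-%m-%d", tz = "UTC"))
}

#' Data-quality assessment (summarization task 1)
#'
#' Verdict is `"good"` when at least `min_pct` percent of the expected
#' readings were captured and at least `min_days` days carry data;
#' otherwise `"insufficient"`.
#'
#' @param series a [glucose_series()].
#' @param expected_days nominal wear period (default 14).
#' @param min_pct capture threshold, percent (default 70).
#' @param min_days active-day threshold (default 10).
#' @return an `agp_finding`.
#' @export
assess_data_quality <- function(series, expected_days = 14,
                                min_pct = 70, min_days = 10) {
  da <- days_active(series)
  pct <- percent_captured(series, expected_days)
  gaps <- series_gaps(series)
  good <- pct >= min_pct && da >= min_days
  facts <- list(days_active = da, pct_captured = pct,
                expected_days = expected_days, n_gaps = nrow(gaps),
                longest_gap = if (nrow(gaps)) max(gaps$minutes) else 0,
                verdict = if (good) "good" else "insufficient")
  s1 <- if (good) {
    sprintf(paste0("Data quality is good: %s%% of expected readings were",
                   " captured over %d active days of a %d-day wear."),
            fmt1(pct), da, expected_days)
  } else {
    sprintf(paste0("Data quality is insufficient for confident",
                   " interpretation: only %s%% of expected readings were",
                   " captured over %d active days of a %d-day wear."),
            fmt1(pct), da, expected_days)
  }
  s2 <- if (nrow(gaps) > 0) {
    sprintf(paste0("There are %d sensor gap(s), the longest lasting %s",
                   " minutes; intervals without data are excluded from all",
                   " statements rather than filled in."),
            nrow(gaps), fmt1(facts$longest_gap))
  } else {
    "The record is contiguous with no sensor gaps."
  }
  new_finding("data_quality", facts, c(s1, s2),
              flags = if (good) character() else "insufficient_data")
}

# Severity mapping for the hyperglycemia narrative; labels are
# threshold-gated so mild elevations are never escalated:
#   none     TAR>180 = 0
#   mild     TAR>180 < 25% and TAR>250 < 5% and no prolonged episode
#   moderate TAR>180 < 50% and TAR>250 < 10% (not mild)
#   notable  otherwise
hyper_severity <- function(tar180, tar250, n_prolonged) {
  if (tar180 == 0) return("none")
  if (tar180 < 25 && tar250 < 5 && n_prolonged == 0) return("mild")
  if (tar180 < 50 && tar250 < 10) return("moderate")
  "notable"
}

#' Hyperglycemia analysis (summarization task 2)
#'
#' Inter-day trend as per-day time above range with the worst `k_worst`
#' days, intraday trend as the clock window where the median AGP curve
#' is highest above 180 mg/dL, and prolonged hyperglycemia as
#' excursions above 250 mg/dL sustained at least 120 minutes.
#'
#' @param series a non-empty [glucose_series()].
#' @param bands optional precomputed [compute_bands()] result.
#' @param k_worst number of worst days to report (default 3).
#' @return an `agp_finding`.
#' @export
analyze_hyperglycemia <- function(series, bands = compute_bands(series),
                                  k_worst = 3) {
  tir <- time_in_ranges(series, "cumulative")
  by_day <- per_day_split(series)
  day_tab <- data.frame(
    date = names(by_day),
    tar180 = vapply(by_day, function(i) 100 * mean(series$gl[i] > 180),
                    numeric(1)),
    tar250 = vapply(by_day, function(i) 100 * mean(series$gl[i] > 250),
                    numeric(1)),
    row.names = NULL
  )
  worst <- day_tab[order(-day_tab$tar180, day_tab$date), ]
  worst <- utils::head(worst[worst$tar180 > 0, ], k_worst)
  eps <- detect_episodes(series, agp_conventions$level2_hyper, "above",
                         min_duration = agp_conventions$episode_prolonged)
  high_bins <- which(!is.na(bands$p50) & bands$p50 > 180)
  sev <- hyper_severity(tir[["pct_above_180"]], tir[["pct_above_250"]],
                        nrow(eps))
  facts <- list(tar180 = tir[["pct_above_180"]],
                tar250 = tir[["pct_above_250"]],
                per_day = day_tab, worst_days = worst$date,
                prolonged_episodes = eps, severity = sev,
                high_median_clock = bands$clock[high_bins])
  s <- character()
  s[1] <- if (sev == "none") {
    "No readings above 180 mg/dL were recorded; hyperglycemia is not a feature of this record."
  } else {
    sprintf(paste0("Time above 180 mg/dL is %s%% (of which %s%% above",
                   " 250 mg/dL); the hyperglycemia burden is %s."),
            fmt1(facts$tar180), fmt1(facts$tar250), sev)
  }
  if (nrow(worst) > 0) {
    s <- c(s, sprintf(
      "The highest daily time above range occurred on %s (%s%% above 180 mg/dL).",
      worst$date[1], fmt1(worst$tar180[1])))
  }
  if (length(high_bins) > 0) {
    b <- high_bins[which.max(bands$p50[high_bins])]
    s <- c(s, sprintf(
      paste0("The median profile exceeds 180 mg/dL around %s, where the",
             " median reaches %s mg/dL."),
      bands$clock[b], fmt1(bands$p50[b])))
  }
  if (nrow(eps) > 0) {
    s <- c(s, sprintf(
      paste0("%d prolonged hyperglycemic episode(s) above 250 mg/dL",
             " lasting at least 120 minutes were detected, the longest",
             " %s minutes."),
      nrow(eps), fmt1(max(eps$duration))))
  } else if (sev != "none") {
    s <- c(s, "No prolonged excursion above 250 mg/dL lasting 120 minutes or more was detected in the recorded data.")
  }
  if (length(s) < 2) {
    s <- c(s, "Glucose remained at or below the 180 mg/dL target boundary throughout the recorded data.")
  }
  flags <- c(if (sev %in% c("moderate", "notable")) "hyperglycemia_burden",
             if (nrow(eps) > 0) "prolonged_hyperglycemia")
  new_finding("hyperglycemia", facts, s, flags = flags %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hypoglycemia analysis (summarization task 3)
#'
#' Episodes below 70 mg/dL sustained at least 15 minutes, with level-2
#' (< 54 mg/dL), prolonged (>= 120 min) and nocturnal (any overlap with
#' 00:00-06:00) flags.  Nocturnal and level-2 episodes always surface
#' in the narrative regardless of how few there are — clinicians
#' prioritize them — and overnight readings approaching the threshold
#' (70-79 mg/dL between 00:00 and 06:00) are reported as near-misses.
#'
#' @param series a non-empty [glucose_series()].
#' @return an `agp_finding`.
#' @export
analyze_hypoglycemia <- function(series) {
  eps <- detect_episodes(series, agp_conventions$range_low, "below")
  tbr <- time_in_ranges(series, "cumulative")[["pct_below_70"]]
  clock_min <- as.numeric(series$time) %% 86400 / 60
  noct <- clock_min >= agp_conventions$nocturnal_window[1] * 60 &
    clock_min < agp_conventions$nocturnal_window[2] * 60
  nm_band <- agp_conventions$near_miss_band
  near_miss <- noct & series$gl >= nm_band[1] & series$gl < nm_band[2]
  n_gaps <- nrow(series_gaps(series))
  facts <- list(episodes = eps, tbr = tbr,
                n_episodes = nrow(eps),
                n_level2 = sum(eps$level == 2),
                n_nocturnal = sum(eps$nocturnal),
                n_prolonged = sum(eps$prolonged),
                n_near_miss = sum(near_miss),
                near_miss_days = length(unique(format(
                  series$time[near_miss], "%Y-%m-%d", tz = "UTC"))))
  s <- character()
  # priority order: level-2 and nocturnal events lead, then totals,
  # then near-misses, then the (gap-qualified) all-clear
  if (facts$n_level2 > 0) {
    worst <- min(eps$extremum)
    s <- c(s, sprintf(
      paste0("%d clinically significant level-2 episode(s) below",
             " 54 mg/dL occurred, with a nadir of %s mg/dL; these warrant",
             " prompt review."),
      facts$n_level2, fmt1(worst)))
  }
  if (facts$n_nocturnal > 0) {
    first_noct <- eps[eps$nocturnal, ][1, ]
    s <- c(s, sprintf(
      paste0("%d episode(s) overlapped the overnight window",
             " (00:00-06:00), including one starting %s lasting %s",
             " minutes; nocturnal hypoglycemia is a priority finding."),
      facts$n_nocturnal, format(first_noct$start, "%Y-%m-%d %H:%M"),
      fmt1(first_noct$duration)))
  }
  if (facts$n_episodes > 0) {
    s <- c(s, sprintf(
      paste0("In total %d hypoglycemic episode(s) below 70 mg/dL were",
             " detected (%d prolonged beyond 120 minutes); time below",
             " 70 mg/dL is %s%% of readings."),
      facts$n_episodes, facts$n_prolonged, fmt1(tbr)))
  } else {
    s <- c(s, if (n_gaps > 0) {
      "No hypoglycemic episode below 70 mg/dL was detected in the recorded data; periods of missing data cannot be assessed."
    } else {
      "No hypoglycemic episode below 70 mg/dL was detected."
    })
  }
  if (facts$n_near_miss > 0) {
    s <- c(s, sprintf(
      paste0("Overnight glucose approached the hypoglycemic threshold",
             " (70-79 mg/dL) in %d reading(s) across %d night(s) without",
             " crossing it."),
      facts$n_near_miss, facts$near_miss_days))
  }
  if (length(s) < 2) {
    s <- c(s, sprintf(
      "Time below 70 mg/dL is %s%% of readings over the wear period.",
      fmt1(tbr)))
  }
  flags <- c(if (facts$n_level2 > 0) "level2_hypoglycemia",
             if (facts$n_nocturnal > 0) "nocturnal_hypoglycemia",
             if (facts$n_episodes > 0) "hypoglycemia")
  new_finding("hypoglycemia", facts, s, flags = flags %||% character())
}

#' Glycemic variability analysis (summarization task 4)
#'
#' Overall and per-day coefficient of variation, days exceeding the 36%
#' stability cut, and the clock window of maximal interquartile range
#' from the AGP bands.  The narrative never calls control "stable" when
#' the GMI is at or above 8%: low variability around a persistently
#' high mean is not stability.
#'
#' @param series a non-empty [glucose_series()].
#' @param bands optional precomputed [compute_bands()] result.
#' @return an `agp_finding`.
#' @export
analyze_variability <- function(series, bands = compute_bands(series)) {
  cv_all <- cv_glucose(series)
  gmi <- gmi_from_mean(mean_glucose(series))
  by_day <- per_day_split(series)
  day_cv <- vapply(by_day, function(i) {
    g <- series$gl[i]
    if (length(g) < 2 || mean(g) == 0) return(0)
    100 * stats::sd(g) * sqrt((length(g) - 1) / length(g)) / mean(g)
  }, numeric(1))
  cut <- agp_conventions$high_cv
  high_days <- names(day_cv)[day_cv > cut]
  prof <- iqr_profile(bands)
  w <- attr(prof, "max_window")
  facts <- list(cv = cv_all, gmi = gmi, per_day_cv = day_cv,
                high_cv_days = high_days, high_cv_cut = cut,
                max_iqr = attr(prof, "max_iqr"),
                max_iqr_start = sprintf("%02d:%02d", w[["start"]] %/% 60,
                                        w[["start"]] %% 60),
                max_iqr_end = sprintf("%02d:%02d", (w[["end"]] %% 1440) %/% 60,
                                      w[["end"]] %% 60))
  s <- character()
  s[1] <- if (cv_all > cut) {
    sprintf(paste0("Glycemic variability is high: the overall coefficient",
                   " of variation is %s%%, above the %s%% stability",
                   " threshold."), fmt1(cv_all), fmt1(cut))
  } else if (gmi >= 8) {
    sprintf(paste0("The coefficient of variation is %s%%, but glucose sits",
                   " persistently in the hyperglycemic range (GMI %s%%),",
                   " so low variability here does not indicate good",
                   " control."), fmt1(cv_all), fmt1(gmi))
  } else {
    sprintf(paste0("Glycemic variability is relatively stable: the overall",
                   " coefficient of variation is %s%%, below the %s%%",
                   " threshold."), fmt1(cv_all), fmt1(cut))
  }
  s[2] <- if (length(high_days) > 0) {
    sprintf("%d day(s) exceeded a within-day CV of %s%%, the first on %s.",
            length(high_days), fmt1(cut), high_days[1])
  } else {
    sprintf("No single day exceeded a within-day CV of %s%%.", fmt1(cut))
  }
  s[3] <- sprintf(
    paste0("The interquartile range of the daily profile is widest between",
           " %s and %s (IQR %s mg/dL)."),
    facts$max_iqr_start, facts$max_iqr_end, fmt1(facts$max_iqr))
  flags <- c(if (cv_all > cut) "high_variability",
             if (gmi >= 8) "persistent_hyperglycemia")
  new_finding("variability", facts, s, flags = flags %||% character())
}

#' Main clinical concern (summarization task 5)
#'
#' A fixed rule cascade, first match wins:
#' 1. any level-2 hypoglycemic episode, or time below 70 mg/dL >= 4% —
#'    hypoglycemia;
#' 2. any nocturnal hypoglycemic episode — nocturnal hypoglycemia;
#' 3. time in range < 70% or GMI >= 8% — hyperglycemia burden;
#' 4. CV > 36% — variability;
#' 5. otherwise — meets targets.
#'
#' The narrative always restates the GMI and time in range, whatever
#' the concern, so the headline metrics are never dropped from the
#' takeaway.
#'
#' @param report a [metric_report()].
#' @param findings list of the four task findings, named
#'   `data_quality`, `hyperglycemia`, `hypoglycemia`, `variability`.
#' @return an `agp_finding`.
#' @export
main_clinical_concern <- function(report, findings) {
  stopifnot(inherits(report, "metric_report"))
  need <- c("data_quality", "hyperglycemia", "hypoglycemia", "variability")
  if (!all(need %in% names(findings))) {
    stop("findings must contain: ", paste(need, collapse = ", "))
  }
  hf <- findings$hypoglycemia$facts
  tir <- report$pct_70_180
  tbr <- report$pct_below_70
  gmi <- report$gmi
  cv <- report$cv
  concern <- if (hf$n_level2 > 0 || tbr >= 4) {
    "hypoglycemia"
  } else if (hf$n_nocturnal > 0) {
    "nocturnal_hypoglycemia"
  } else if (tir < 70 || gmi >= 8) {
    "hyperglycemia_burden"
  } else if (cv > agp_conventions$high_cv) {
    "variability"
  } else {
    "meets_targets"
  }
  headline <- switch(
    concern,
    hypoglycemia = sprintf(
      paste0("The primary clinical concern is hypoglycemia: %d level-2",
             " episode(s) below 54 mg/dL and %s%% of readings below",
             " 70 mg/dL."), hf$n_level2, fmt1(tbr)),
    nocturnal_hypoglycemia = sprintf(
      paste0("The primary clinical concern is nocturnal hypoglycemia:",
             " %d overnight episode(s) below 70 mg/dL."), hf$n_nocturnal),
    hyperglycemia_burden = sprintf(
      paste0("The primary clinical concern is the hyperglycemia burden:",
             " time in range is %s%% and time above 180 mg/dL is %s%%."),
      fmt1(tir), fmt1(report$pct_above_180)),
    variability = sprintf(
      paste0("The primary clinical concern is glycemic variability: the",
             " coefficient of variation is %s%%, above the %s%%",
             " threshold."), fmt1(cv), fmt1(agp_conventions$high_cv)),
    meets_targets = sprintf(
      paste0("No primary clinical concern: the record meets consensus",
             " targets, and the current regimen can be reinforced."))
  )
  anchor <- sprintf(
    "Overall the GMI is %s%% with %s%% time in range (70-180 mg/dL).",
    fmt1(gmi), fmt1(tir))
  facts <- list(concern = concern, gmi = gmi, tir = tir, tbr = tbr,
                cv = cv, n_level2 = hf$n_level2,
                n_nocturnal = hf$n_nocturnal)
  new_finding("main_concern", facts, c(headline, anchor),
              flags = if (concern == "meets_targets") character() else concern)
}

#' Run all five summarization tasks on a series
#'
#' @param series a non-empty [glucose_series()].
#' @param expected_days nominal wear period (default 14).
#' @return named list of five `agp_finding` objects (`data_quality`,
#'   `hyperglycemia`, `hypoglycemia`, `variability`, `main_concern`).
#' @export
summarize_case <- function(series, expected_days = 14) {
  bands <- compute_bands(series)
  findings <- list(
    data_quality = assess_data_quality(series, expected_days),
    hyperglycemia = analyze_hyperglycemia(series, bands),
    hypoglycemia = analyze_hypoglycemia(series),
    variability = analyze_variability(series, bands)
  )
  report <- metric_report(series, expected_days)
  findings$main_concern <- main_clinical_concern(report, findings)
  findings
}
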