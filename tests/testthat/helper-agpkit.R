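# Shared fixtures, built in code.

# A series on a regular grid starting at midnight.
make_series <- function(gl, start = "2024-03-01 00:00:00", interval = 5) {
  t0 <- as.POSIXct(start, tz = "UTC")
  glucose_series(t0 + (seq_along(gl) - 1) * interval * 60, gl,
                 interval = interval)
}

# Random valid series; caller is responsible for the seed.
random_series <- function(n, interval = 5) {
  make_series(round(runif(n, 40, 400), 1), interval = interval)
}

# A random-walk series with occasional gaps, for episode fixtures.
random_walk_series <- function(n, start_gl = 120, sd = 20,
                               gap_prob = 0.05, interval = 5) {
  gl <- pmin(pmax(cumsum(c(start_gl, rnorm(n - 1, 0, sd))), 39), 401)
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  steps <- ifelse(runif(n - 1) < gap_prob,
                  sample(c(2, 5, 10, 20), n - 1, replace = TRUE), 1)
  tm <- t0 + cumsum(c(0, steps)) * interval * 60
  glucose_series(tm, round(gl, 1), interval = interval)
}

# The default generated suite is expensive (~1 min); build it once per
# test run and reuse it across test files.
.suite_cache <- new.env(parent = emptyenv())
default_suite <- function() {
  if (is.null(.suite_cache$suite)) {
    t0 <- Sys.time()
    suite <- generate_suite()
    gen_secs <- as.numeric(Sys.time() - t0, units = "secs")
    t0 <- Sys.time()
    reports <- lapply(suite, function(cs) metric_report(cs$series))
    metric_secs <- as.numeric(Sys.time() - t0, units = "secs")
    .suite_cache$suite <- suite
    .suite_cache$reports <- reports
    .suite_cache$gen_secs <- gen_secs
    .suite_cache$metric_secs <- metric_secs
  }
  .suite_cache$suite
}
default_suite_reports <- function() {
  default_suite()
  .suite_cache$reports
}
default_suite_timing <- function() {
  default_suite()
  c(generate = .suite_cache$gen_secs, metrics = .suite_cache$metric_secs)
}

# Brute-force metric oracle: naive loops, no shared code with the
# implementation.
oracle_metrics <- function(gl) {
  n <- length(gl)
  s <- 0
  for (x in gl) s <- s + x
  m <- s / n
  ss <- 0
  for (x in gl) ss <- ss + (x - m)^2
  cv <- 100 * sqrt(ss / n) / m
  c250 <- 0; c180 <- 0; band <- 0; tir <- 0; b70 <- 0; b54 <- 0
  for (x in gl) {
    if (x > 250) c250 <- c250 + 1
    if (x > 180) c180 <- c180 + 1
    if (x > 180 && x <= 250) band <- band + 1
    if (x >= 70 && x <= 180) tir <- tir + 1
    if (x < 70) b70 <- b70 + 1
    if (x < 54) b54 <- b54 + 1
  }
  list(mean = m, cv = cv,
       pct_above_250 = 100 * c250 / n, pct_above_180 = 100 * c180 / n,
       banded_180 = 100 * band / n, pct_70_180 = 100 * tir / n,
       pct_below_70 = 100 * b70 / n, pct_below_54 = 100 * b54 / n)
}

# Independent episode oracle: pairwise split rules over excursion
# readings rather than a one-pass scan.
oracle_episodes <- function(series, threshold, direction,
                            min_duration = 15, end_recovery = 15,
                            max_gap = 30) {
  iv <- series_interval(series)
  tm <- as.numeric(series$time) / 60
  out <- if (direction == "below") series$gl < threshold else
    series$gl > threshold
  oi <- which(out)
  if (length(oi) == 0) return(NULL)
  new_ep <- logical(length(oi))
  new_ep[1] <- TRUE
  if (length(oi) > 1) {
    for (j in 2:length(oi)) {
      a <- oi[j - 1]; b <- oi[j]
      gap_inside <- any(diff(tm[a:b]) > max_gap)
      between <- setdiff(seq(a, b), c(a, b))
      between <- between[!out[between]]
      recovered <- length(between) > 0 &&
        any(tm[between] - tm[a] >= end_recovery)
      new_ep[j] <- gap_inside || recovered
    }
  }
  grp <- cumsum(new_ep)
  eps <- lapply(unique(grp), function(g) {
    idx <- oi[grp == g]
    gl <- series$gl[idx]
    data.frame(start = series$time[idx[1]],
               end = series$time[idx[length(idx)]] + iv * 60,
               duration = tm[idx[length(idx)]] - tm[idx[1]] + iv,
               extremum = if (direction == "below") min(gl) else max(gl))
  })
  res <- do.call(rbind, eps)
  res[res$duration >= min_duration, , drop = FALSE]
}

# Literal transcription of the two-rater binary AC1 formula.
oracle_ac1 <- function(a, b) {
  n <- length(a)
  pa <- sum(a == b) / n
  p_hat <- (sum(a) / n + sum(b) / n) / 2
  pe <- 2 * p_hat * (1 - p_hat)
  (pa - pe) / (1 - pe)
}

# Count sentences in a rendered narrative.
n_sentences <- function(text) {
  length(gregexpr("[.!?](\\s|$)", text)[[1]])
}
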