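#' Patient model parameters
#'
#' Parameters of the Bergman-type glucose-insulin minimal model used to
#' generate synthetic type 1 diabetes traces.  The model is
#'
#' \deqn{dG/dt = -p_1 (G - G_b) - X G + R_a(t)}
#' \deqn{dX/dt = -p_2 X + p_3 (I - I_b)}
#' \deqn{dI/dt = -k_i (I - s \cdot I_b)}
#' \deqn{dQ_1/dt = -k_a Q_1, \quad dQ_2/dt = k_a (Q_1 - Q_2)}
#'
#' with meal appearance \eqn{R_a = f_{carb} k_a Q_2} (a two-compartment
#' absorption chain; a meal of `c` grams adds `c` to `Q1`), and insulin
#' delivery scaled throughout by the dimensionless `dose_scale` \eqn{s}:
#' the effective basal level is `dose_scale * Ib` and each bolus adds
#' `dose_scale * units * bolus_gain` to plasma insulin, decaying with
#' rate `ki`.  At `dose_scale = 1` with no meals the state
#' `(Gb, 0, Ib, 0, 0)` is an exact equilibrium.  `dose_scale` is the one
#' calibration knob: larger values mean more insulin, hence lower mean
#' glucose, so realized mean glucose is monotone decreasing in it.
#'
#' @param Gb basal plasma glucose, mg/dL (70-300).
#' @param p1 glucose effectiveness, 1/min.
#' @param p2 insulin action decay rate, 1/min.
#' @param p3 insulin sensitivity gain, 1/min per µU/mL.
#' @param Ib basal plasma insulin, µU/mL.
#' @param ka meal absorption rate, 1/min.
#' @param f_carb carbohydrate-to-glucose appearance scale, mg/dL per g.
#' @param ki insulin absorption/decay rate, 1/min.
#' @param bolus_gain plasma insulin increment per unit of bolus insulin,
#'   µU/mL per U.
#' @param dose_scale dimensionless multiplier on all insulin delivery
#'   (0.1-10); the knob [calibrate_to_gmi()] tunes.
#' @return a `patient_params` list.
#' @export
patient_params <- function(Gb = 120, p1 = 0.010, p2 = 0.020, p3 = 2.2e-5,
                           Ib = 12, ka = 0.035, f_carb = 4.5, ki = 0.012,
                           bolus_gain = 9, dose_scale = 1) {
  p <- list(Gb = Gb, p1 = p1, p2 = p2, p3 = p3, Ib = Ib, ka = ka,
            f_carb = f_carb, ki = ki, bolus_gain = bolus_gain,
            dose_scale = dose_scale)
  rates <- c(p1, p2, p3, ka, ki)
  if (any(rates <= 0)) stop("all rate constants must be > 0")
  if (Gb < 70 || Gb > 300) stop("Gb must lie in [70, 300] mg/dL")
  if (dose_scale < 0.1 || dose_scale > 10) {
    stop("dose_scale must lie in [0.1, 10]")
  }
  class(p) <- "patient_params"
  p
}

#' CGM sensor model parameters
#'
#' The sensing model applied to the dense plasma trace: a first-order
#' interstitial lag with time constant `tau_lag`, multiplicative AR(1)
#' Gaussian noise with stationary coefficient of variation `noise_cv`
#' and autocorrelation `ar_phi` between consecutive samples, then
#' clamping to the sensor reporting range.
#'
#' @param tau_lag interstitial lag time constant, minutes (>= 0).
#' @param noise_cv stationary noise coefficient of variation, fraction
#'   in \[0, 0.2\].
#' @param ar_phi AR(1) autocorrelation of the noise, in \[0, 1).
#' @return a `sensor_params` list.
#' @export
sensor_params <- function(tau_lag = 10, noise_cv = 0.05, ar_phi = 0.7) {
  if (tau_lag < 0) stop("tau_lag must be >= 0")
  if (noise_cv < 0 || noise_cv > 0.2) stop("noise_cv must lie in [0, 0.2]")
  if (ar_phi < 0 || ar_phi >= 1) stop("ar_phi must lie in [0, 1)")
  structure(list(tau_lag = tau_lag, noise_cv = noise_cv, ar_phi = ar_phi),
            class = "sensor_params")
}

#' Per-case generation recipe
#'
#' Everything needed to reproduce one synthetic case byte-for-byte:
#' duration, sampling interval, the GMI the case is calibrated to, the
#' meal/bolus schedule, the missingness mechanism, and the seed.  All
#' randomness (meal jitter, sensor noise, gap placement) derives from
#' `seed` through fixed per-stage substreams, so adding draws to one
#' stage never shifts another.
#'
#' @param case_id identifier string.
#' @param duration_days length of the case in days (default 14).
#' @param interval_min sampling interval in minutes (default 5,
#'   i.e. 288 readings/day).
#' @param target_gmi Glucose Management Indicator the case is calibrated
#'   to, percent, in \[5, 12\].
#' @param meal_schedule data.frame with columns `clock` ("HH:MM"),
#'   `carbs` (g), `carb_jitter` (g, s.d. of the per-meal perturbation)
#'   and `time_jitter` (min, half-width of the uniform timing
#'   perturbation).  Default: three daily meals of 45/60/75 g.
#' @param carb_ratio grams of carbohydrate covered per unit of bolus
#'   insulin (default 10).
#' @param bolus_offset_min minutes between meal start and bolus
#'   (default 0).
#' @param gap_prob_per_day probability that a day contains one sensor
#'   gap (default 0.3).
#' @param gap_minutes length range of a gap, minutes (default 30-120).
#' @param start_date calendar date of day 1 (midnight anchor).
#' @param seed integer seed; fixed seed implies fully reproducible
#'   generation.
#' @return a `case_config` list.
#' @export
case_config <- function(case_id = "case01", duration_days = 14,
                        interval_min = 5, target_gmi = 7.0,
                        meal_schedule = default_meal_schedule(),
                        carb_ratio = 10, bolus_offset_min = 0,
                        gap_prob_per_day = 0.3, gap_minutes = c(30, 120),
                        start_date = "2024-03-01", seed = 1L) {
  stopifnot(duration_days >= 1, interval_min > 0,
            is.data.frame(meal_schedule),
            all(c("clock", "carbs", "carb_jitter", "time_jitter") %in%
                  names(meal_schedule)),
            carb_ratio > 0, gap_prob_per_day >= 0, gap_prob_per_day <= 1,
            length(gap_minutes) == 2, gap_minutes[1] <= gap_minutes[2])
  if (target_gmi < 5 || target_gmi > 12) {
    stop("target_gmi must lie in [5, 12] percent")
  }
  structure(list(case_id = case_id, duration_days = duration_days,
                 interval_min = interval_min, target_gmi = target_gmi,
                 meal_schedule = meal_schedule, carb_ratio = carb_ratio,
                 bolus_offset_min = bolus_offset_min,
                 gap_prob_per_day = gap_prob_per_day,
                 gap_minutes = gap_minutes, start_date = start_date,
                 seed = as.integer(seed)),
            class = "case_config")
}

#' @rdname case_config
#' @export
default_meal_schedule <- function() {
  data.frame(clock = c("07:30", "12:30", "18:30"),
             carbs = c(45, 60, 75),
             carb_jitter = c(8, 12, 15),
             time_jitter = c(20, 25, 30))
}

# Per-stage substream seeds: meal jitter (1), sensor noise (2), gaps (3).
# Kept below 2^31 - 1 so they are valid R integer seeds.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}

# Local seeded evaluation that never disturbs the caller's RNG state.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}

# Realized meal/bolus event table for a case: jittered meal times and
# carbs, plus the bolus each meal triggers.  Deterministic given the
# config seed (stage 1).
meal_events <- function(params, config) {
  sched <- config$meal_schedule
  n_meal <- nrow(sched)
  days <- config$duration_days
  if (n_meal == 0 || days == 0) {
    return(data.frame(time_min = numeric(), carbs = numeric(),
                      bolus_units = numeric()))
  }
  clock_min <- vapply(strsplit(sched$clock, ":"), function(p) {
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
  with_stage_seed(config$seed, 1L, {
    # draws in fixed order: all time jitters, then all carb jitters
    tj <- stats::runif(days * n_meal, -1, 1) *
      rep(sched$time_jitter, times = days)
    cj <- stats::rnorm(days * n_meal) *
      rep(sched$carb_jitter, times = days)
    # rounded to whole minutes so events land on the solver output grid
    time_min <- round(rep((seq_len(days) - 1) * 1440, each = n_meal) +
                        rep(clock_min, times = days) + tj)
    carbs <- pmax(rep(sched$carbs, times = days) + cj, 5)
    data.frame(time_min = time_min, carbs = carbs,
               bolus_units = carbs / config$carb_ratio)
  })
}

#' Integrate the patient model to a dense glucose trace
#'
#' Solves the minimal-model ODE system (see [patient_params()]) over the
#' case duration at 1-minute resolution, with the case's jittered
#' meal/bolus schedule applied as impulse events.  The trace is the
#' noise-free plasma glucose; sensor effects are applied separately by
#' [sample_sensor()].
#'
#' @param params a [patient_params()].
#' @param config a [case_config()].
#' @return data.frame with columns `time_min` (minutes since the case
#'   start midnight, step 1) and `G` (plasma glucose, mg/dL, unclamped).
#' @export
simulate_patient <- function(params, config) {
  stopifnot(inherits(params, "patient_params"),
            inherits(config, "case_config"))
  total_min <- config$duration_days * 1440
  meals <- meal_events(params, config)

  deriv <- function(t, y, p) {
    G <- y[1]; X <- y[2]; I <- y[3]; Q1 <- y[4]; Q2 <- y[5]
    Ra <- p$f_carb * p$ka * Q2
    list(c(
      -p$p1 * (G - p$Gb) - X * G + Ra,
      -p$p2 * X + p$p3 * (I - p$Ib),
      -p$ki * (I - p$dose_scale * p$Ib),
      -p$ka * Q1,
      p$ka * (Q1 - Q2)
    ))
  }

  y0 <- c(G = params$Gb, X = 0, I = params$dose_scale * params$Ib,
          Q1 = 0, Q2 = 0)
  events <- NULL
  if (nrow(meals) > 0) {
    ev <- rbind(
      data.frame(var = "Q1", time = meals$time_min,
                 value = meals$carbs, method = "add"),
      data.frame(var = "I",
                 time = meals$time_min + config$bolus_offset_min,
                 value = params$dose_scale * params$bolus_gain *
                   meals$bolus_units,
                 method = "add")
    )
    ev <- ev[ev$time >= 0 & ev$time <= total_min, ]
    ev <- ev[order(ev$time, ev$var), ]
    events <- list(data = ev)
  }
  sol <- deSolve::ode(y0, times = seq(0, total_min), func = deriv,
                      parms = params, events = events, method = "lsoda")
  G <- sol[, "G"]
  if (any(!is.finite(G))) {
    stop("patient model produced a non-finite state; reject parameters")
  }
  if (any(G <= 0)) {
    stop("patient model produced non-positive glucose; reject parameters")
  }
  out <- data.frame(time_min = as.numeric(sol[, "time"]), G = G)
  out[!duplicated(out$time_min) & out$time_min %% 1 == 0, ]
}

#' Apply the CGM sensing model to a dense trace
#'
#' First-order interstitial lag, subsampling onto the case's grid,
#' multiplicative AR(1) Gaussian noise (stage-2 substream of the case
#' seed), and clamping to the sensor range.  Produces
#' `1440 / interval_min` readings per day (288/day at the default 5-min
#' interval) before any missingness.
#'
#' @param trace output of [simulate_patient()].
#' @param sensor a [sensor_params()].
#' @param config a [case_config()].
#' @return a [glucose_series()].
#' @export
sample_sensor <- function(trace, sensor, config) {
  stopifnot(inherits(sensor, "sensor_params"),
            inherits(config, "case_config"))
  total_min <- config$duration_days * 1440
  if (max(trace$time_min) < total_min - config$interval_min) {
    stop("trace does not cover the sampling window")
  }
  G <- trace$G
  if (sensor$tau_lag > 0) {
    # exact discretization of dGi/dt = (G - Gi)/tau on the 1-min grid
    a <- exp(-1 / sensor$tau_lag)
    Gi <- stats::filter(G * (1 - a), filter = a, method = "recursive",
                        init = G[1])
    G <- as.numeric(Gi)
  }
  grid_min <- seq(0, total_min - config$interval_min,
                  by = config$interval_min)
  g <- G[match(grid_min, trace$time_min)]
  n <- length(g)
  if (sensor$noise_cv > 0) {
    e <- with_stage_seed(config$seed, 2L, {
      z <- stats::rnorm(n)
      # stationary start: e_1 ~ N(0, cv^2), then the AR(1) recursion
      x <- z * sensor$noise_cv * sqrt(1 - sensor$ar_phi^2)
      x[1] <- z[1] * sensor$noise_cv
      as.numeric(stats::filter(x, filter = sensor$ar_phi,
                               method = "recursive"))
    })
    g <- g * (1 + e)
  }
  g <- round(clamp_glucose(g, warn = FALSE), 1)
  start <- as.POSIXct(config$start_date, tz = "UTC")
  glucose_series(start + grid_min * 60, g, interval = config$interval_min)
}

#' Remove sensor gaps from a series
#'
#' For each case day, with probability `gap_prob_per_day`, one
#' contiguous block of readings is dropped; gap length is uniform over
#' `gap_minutes` and the gap start is uniform over the day.  Draws come
#' from the stage-3 substream of the case seed, so output is
#' deterministic given the config.  Nothing is ever imputed in place of
#' a gap.
#'
#' @param series a [glucose_series()].
#' @param config a [case_config()].
#' @return the series with gap readings removed.
#' @export
inject_missingness <- function(series, config) {
  stopifnot(inherits(series, "glucose_series"),
            inherits(config, "case_config"))
  if (nrow(series) == 0 || config$gap_prob_per_day == 0) return(series)
  days <- config$duration_days
  drops <- with_stage_seed(config$seed, 3L, {
    # fixed order: per-day occurrence flags, then starts, then lengths
    hit <- stats::runif(days) < config$gap_prob_per_day
    starts <- stats::runif(days, 0, 1440)
    lens <- stats::runif(days, config$gap_minutes[1],
                         config$gap_minutes[2])
    list(hit = hit, starts = starts, lens = lens)
  })
  start0 <- as.POSIXct(config$start_date, tz = "UTC")
  rel_min <- as.numeric(series$time - start0, units = "mins")
  keep <- rep(TRUE, nrow(series))
  for (d in which(drops$hit)) {
    g0 <- (d - 1) * 1440 + drops$starts[d]
    keep <- keep & !(rel_min >= g0 & rel_min < g0 + drops$lens[d])
  }
  out <- glucose_series(series$time[keep], series$gl[keep],
                        interval = series_interval(series))
  out
}

#' Calibrate the insulin dose scale to a target GMI
#'
#' Bisects on `dose_scale` until the noise-free 14-day trace (clamped to
#' the sensor range, since that is what the sensor can report) has a
#' mean glucose whose implied GMI is within `tol` of
#' `config$target_gmi`.  The GMI target is inverted to a mean-glucose
#' target analytically via [mean_from_gmi()].  Deterministic given the
#' config seed (the only randomness is the meal jitter, which is
#' seed-fixed).
#'
#' @param target_gmi target GMI in percent (default: the config's).
#' @param params starting [patient_params()].
#' @param config a [case_config()].
#' @param tol GMI tolerance, percentage points (default 0.05).
#' @param max_iter bisection iteration cap (default 50).
#' @return `params` with `dose_scale` replaced by the calibrated value.
#' @export
calibrate_to_gmi <- function(target_gmi = config$target_gmi, params,
                             config, tol = 0.05, max_iter = 50) {
  stopifnot(inherits(params, "patient_params"),
            inherits(config, "case_config"))
  realized <- function(ds) {
    p <- params
    p$dose_scale <- ds
    tr <- simulate_patient(p, config)
    gmi_from_mean(mean(clamp_glucose(tr$G, warn = FALSE)))
  }
  lo <- 0.1; hi <- 10            # dose_scale bounds; GMI decreasing in ds
  g_lo <- realized(lo); g_hi <- realized(hi)
  if (target_gmi > g_lo + tol || target_gmi < g_hi - tol) {
    stop(sprintf(
      "target GMI %.2f unreachable: achievable interval is [%.2f, %.2f]",
      target_gmi, g_hi, g_lo))
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)         # geometric midpoint: ds acts on a log scale
    g_mid <- realized(mid)
    if (abs(g_mid - target_gmi) <= tol) {
      params$dose_scale <- mid
      return(params)
    }
    if (g_mid > target_gmi) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "calibration did not converge to GMI %.2f within %d iterations",
    target_gmi, max_iter))
}

#' Generate one synthetic case end to end
#'
#' Calibrates `dose_scale` to the config's target GMI, integrates the
#' patient model, applies the sensing model, and injects missingness.
#'
#' @param config a [case_config()].
#' @param params a [patient_params()] (pre-calibration).
#' @param sensor a [sensor_params()].
#' @return list with elements `config`, `params` (calibrated) and
#'   `series` (a [glucose_series()]).
#' @export
generate_case <- function(config, params = patient_params(),
                          sensor = sensor_params()) {
  params <- calibrate_to_gmi(config$target_gmi, params, config)
  trace <- simulate_patient(params, config)
  series <- sample_sensor(trace, sensor, config)
  series <- inject_missingness(series, config)
  list(config = config, params = params, series = series)
}

#' Generate a suite of cases spanning a GMI spectrum
#'
#' Target GMIs are evenly spaced from `gmi_low` to `gmi_high` inclusive;
#' case seeds are `base_seed + 1 ... base_seed + n`, so the whole suite
#' is reproducible from `base_seed`.  Defaults produce the study-scale
#' design: 10 cases of 14 days at 5-minute sampling spanning GMI 6.0%
#' to 9.0%.
#'
#' @param n_cases number of cases (>= 2; default 10).
#' @param gmi_low,gmi_high endpoints of the GMI spectrum, percent
#'   (defaults 6.0 and 9.0).
#' @param base_seed integer; case `i` uses seed `base_seed + i`.
#' @param params,sensor shared model parameters.
#' @param ... further arguments passed to [case_config()] (e.g.
#'   `duration_days`).
#' @return list of per-case lists as returned by [generate_case()].
#' @export
generate_suite <- function(n_cases = 10, gmi_low = 6.0, gmi_high = 9.0,
                           base_seed = 1L, params = patient_params(),
                           sensor = sensor_params(), ...) {
  stopifnot(n_cases >= 2, gmi_low < gmi_high)
  targets <- seq(gmi_low, gmi_high, length.out = n_cases)
  lapply(seq_len(n_cases), function(i) {
    cfg <- case_config(case_id = sprintf("case%02d", i),
                       target_gmi = targets[i],
                       seed = as.integer(base_seed) + i, ...)
    generate_case(cfg, params = params, sensor = sensor)
  })
}
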