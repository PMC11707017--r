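# Building blocks for constructed fixtures: a day of in-range glucose
# with excursions patched in at chosen clock minutes.
flat_day <- function(days = 1, gl = 120) rep(gl, 288 * days)
patch <- function(gl, day, clock_min, values) {
  idx <- (day - 1) * 288 + clock_min / 5 + 1 + seq_along(values) - 1
  gl[idx] <- values
  gl
}

test_that("episode scan matches the spec examples", {
  expect_equal(nrow(detect_episodes(make_series(rep(100, 50)), 70, "below")),
               0)
  expect_equal(nrow(detect_episodes(glucose_series(), 70, "below")), 0)

  # four 5-min readings at 60 = 20 min, above the 15-min minimum
  s <- make_series(c(rep(100, 5), rep(60, 4), rep(100, 5)))
  ep <- detect_episodes(s, 70, "below")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration, 20)
  expect_equal(ep$extremum, 60)
  expect_equal(ep$level, 1L)
  expect_false(ep$prolonged)

  # two readings = 10 min: below the minimum duration
  s2 <- make_series(c(rep(100, 5), rep(60, 2), rep(100, 5)))
  expect_equal(nrow(detect_episodes(s2, 70, "below")), 0)
})

test_that("short recoveries merge episodes; full recoveries split them", {
  # 3 low, 2 in-range (10 min < 15), 3 low: one merged episode
  merged <- make_series(c(rep(100, 4), rep(60, 3), rep(100, 2), rep(60, 3),
                          rep(100, 6)))
  ep <- detect_episodes(merged, 70, "below")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration, (8 - 1) * 5 + 5)

  # 3 in-range readings = 15 min recovery: two distinct episodes
  split <- make_series(c(rep(100, 4), rep(60, 3), rep(100, 3), rep(60, 3),
                         rep(100, 6)))
  ep2 <- detect_episodes(split, 70, "below")
  expect_equal(nrow(ep2), 2)
  expect_true(all(ep2$duration == 15))
})

test_that("gaps longer than 30 min censor open episodes", {
  t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
  tm <- t0 + c(0:3, 12:15) * 300          # 40-min hole between the runs
  s <- glucose_series(tm, rep(60, 8))
  ep <- detect_episodes(s, 70, "below")
  expect_equal(nrow(ep), 2)
  expect_true(all(ep$duration == 20))
  # episodes are disjoint and ordered
  expect_true(all(diff(as.numeric(ep$start)) > 0))
  expect_true(all(as.numeric(ep$end[-nrow(ep)]) <=
                    as.numeric(ep$start[-1])))
})

test_that("level and nocturnal flags follow thresholds and the clock", {
  # 20-min dip to 60 at 03:00: level 1, nocturnal
  gl <- patch(flat_day(), 1, 180, rep(60, 4))
  ep <- detect_episodes(make_series(gl), 70, "below")
  expect_equal(ep$level, 1L)
  expect_true(ep$nocturnal)

  # 20-min dip to 50 at 14:00: level 2, not nocturnal
  gl2 <- patch(flat_day(), 1, 840, rep(50, 4))
  ep2 <- detect_episodes(make_series(gl2), 70, "below")
  expect_equal(ep2$level, 2L)
  expect_false(ep2$nocturnal)

  # hyperglycemia above 250 sustained 2 h+ is prolonged level 2
  gl3 <- patch(flat_day(), 1, 600, rep(300, 30))
  ep3 <- detect_episodes(make_series(gl3), 250, "above",
                         min_duration = 120)
  expect_equal(nrow(ep3), 1)
  expect_true(ep3$prolonged)
  expect_equal(ep3$level, 2L)
})

test_that("episode scan matches the independent oracle on random fixtures", {
  set.seed(2024)
  for (i in 1:100) {
    s <- random_walk_series(sample(50:400, 1), sd = 25, gap_prob = 0.08)
    for (dir in c("below", "above")) {
      thr <- if (dir == "below") 70 else 180
      got <- detect_episodes(s, thr, dir)
      want <- oracle_episodes(s, thr, dir)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), nrow(want))
        expect_equal(as.numeric(got$start), as.numeric(want$start))
        expect_equal(as.numeric(got$end), as.numeric(want$end))
        expect_equal(got$duration, want$duration)
        expect_equal(got$extremum, want$extremum)
      }
    }
  }
})

test_that("data quality verdict follows the capture and day thresholds", {
  good <- assess_data_quality(make_series(flat_day(14)), 14)
  expect_equal(good$facts$verdict, "good")
  expect_equal(good$facts$pct_captured, 100)

  half <- assess_data_quality(make_series(flat_day(7)), 14)
  expect_equal(half$facts$verdict, "insufficient")

  empty <- assess_data_quality(glucose_series(), 14)
  expect_equal(empty$facts$verdict, "insufficient")
  expect_equal(empty$facts$days_active, 0)
})

test_that("hyperglycemia analysis gates severity and finds the worst day", {
  quiet <- analyze_hyperglycemia(make_series(flat_day(3)))
  expect_equal(quiet$facts$severity, "none")
  expect_equal(nrow(quiet$facts$prolonged_episodes), 0)

  # one 3-h block at 300 on day 2
  gl <- patch(flat_day(3), 2, 600, rep(300, 36))
  f <- analyze_hyperglycemia(make_series(gl))
  expect_equal(nrow(f$facts$prolonged_episodes), 1)
  expect_equal(format(f$facts$prolonged_episodes$start, "%Y-%m-%d"),
               "2024-03-02")
  expect_equal(f$facts$worst_days[1], "2024-03-02")

  # mild elevation (TAR 8%, nothing above 250) is never "notable"
  gl2 <- c(rep(200, 8), rep(120, 92))
  f2 <- analyze_hyperglycemia(make_series(gl2))
  expect_equal(f2$facts$severity, "mild")
  expect_false(grepl("notable", render_narrative(f2)))
})

test_that("hypoglycemia analysis prioritizes nocturnal and level-2 events", {
  clean <- analyze_hypoglycemia(make_series(flat_day(2)))
  expect_equal(clean$facts$n_episodes, 0)
  expect_equal(clean$facts$n_near_miss, 0)

  noct <- analyze_hypoglycemia(make_series(patch(flat_day(2), 1, 180,
                                                 rep(60, 4))))
  expect_equal(noct$facts$n_episodes, 1)
  expect_equal(noct$facts$n_nocturnal, 1)
  expect_equal(noct$facts$n_level2, 0)
  expect_match(render_narrative(noct), "overnight")

  lvl2 <- analyze_hypoglycemia(make_series(patch(flat_day(2), 1, 840,
                                                 rep(50, 4))))
  expect_equal(lvl2$facts$n_level2, 1)
  expect_equal(lvl2$facts$n_nocturnal, 0)
  expect_match(render_narrative(lvl2), "level-2")

  # overnight readings in [70, 80) are reported as near-misses
  nm <- analyze_hypoglycemia(make_series(patch(flat_day(2), 2, 120,
                                               rep(74, 6))))
  expect_equal(nm$facts$n_episodes, 0)
  expect_equal(nm$facts$n_near_miss, 6)
  expect_match(render_narrative(nm), "approached")
})

test_that("no-hypoglycemia claims are qualified when the record has gaps", {
  gl <- flat_day(2)
  s <- make_series(gl)
  s_gappy <- glucose_series(s$time[-(100:120)], s$gl[-(100:120)])
  f <- analyze_hypoglycemia(s_gappy)
  expect_equal(f$facts$n_episodes, 0)
  expect_match(render_narrative(f), "missing data")
  f2 <- analyze_hypoglycemia(s)
  expect_false(grepl("missing data", render_narrative(f2)))
})

test_that("variability analysis flags high-CV days and guards 'stable'", {
  const <- analyze_variability(make_series(flat_day(3)))
  expect_equal(const$facts$cv, 0)
  expect_equal(length(const$facts$high_cv_days), 0)

  # day 2 alternates 80/240: within-day CV far above 36%
  gl <- flat_day(3)
  gl[289:576] <- rep(c(80, 240), 144)
  f <- analyze_variability(make_series(gl))
  expect_equal(f$facts$high_cv_days, "2024-03-02")
  expect_gt(f$facts$per_day_cv[["2024-03-02"]], 36)

  # persistently hyperglycemic but flat: never called "stable"
  high <- analyze_variability(make_series(flat_day(3, gl = 250)))
  expect_equal(high$facts$cv, 0)
  expect_false(grepl("stable", render_narrative(high), ignore.case = TRUE))
  expect_true("persistent_hyperglycemia" %in% high$flags)

  # in-target and flat: "stable" is allowed
  calm <- analyze_variability(make_series(flat_day(3)))
  expect_match(render_narrative(calm), "stable")
})

test_that("main concern follows the rule cascade in order", {
  concern_for <- function(gl) {
    s <- make_series(gl)
    f <- summarize_case(s, expected_days = days_active(s))
    f$main_concern$facts$concern
  }
  # rule 5: everything at target
  expect_equal(concern_for(flat_day(3)), "meets_targets")
  # rule 1 beats rule 3: TBR 6% wins over imperfect TIR
  gl <- c(rep(60, 6), rep(220, 40), rep(120, 54))
  expect_equal(concern_for(gl), "hypoglycemia")
  # rule 2: a nocturnal dip with TBR < 4% and everything else at target
  gl2 <- patch(flat_day(3), 2, 120, rep(65, 4))
  expect_equal(concern_for(gl2), "nocturnal_hypoglycemia")
  # rule 3: hyperglycemia burden via low TIR, no hypo at all
  gl3 <- c(rep(250, 60), rep(120, 40))
  expect_equal(concern_for(gl3), "hyperglycemia_burden")
  # rule 4: variability alone (CV > 36% with GMI < 8, TIR >= 70)
  gl4 <- rep(c(90, 100, 110, 120, 130, 140, 150, 160, 170, 300), 10)
  expect_equal(concern_for(gl4), "variability")
})

test_that("the takeaway narrative always restates GMI and TIR", {
  for (gl in list(flat_day(3), c(rep(250, 60), rep(120, 40)))) {
    s <- make_series(gl)
    f <- summarize_case(s, expected_days = days_active(s))
    txt <- render_narrative(f$main_concern)
    rep <- metric_report(s, days_active(s))
    expect_match(txt, sprintf("%.1f", rep$gmi), fixed = TRUE)
    expect_match(txt, sprintf("%.1f", rep$pct_70_180), fixed = TRUE)
  }
})

test_that("narratives are deterministic, 2-6 sentences, truncated by priority", {
  s <- make_series(patch(flat_day(3), 2, 120, rep(60, 4)))
  f <- summarize_case(s, expected_days = 3)
  for (task in names(f)) {
    txt <- render_narrative(f[[task]])
    expect_identical(render_narrative(f[[task]]), txt)
    expect_gte(n_sentences(txt), 2)
    expect_lte(n_sentences(txt), 6)
  }
  # a finding with 7 candidate sentences renders only the top 6
  fake <- agpkit:::new_finding("data_quality", list(),
                               sprintf("Sentence %d.", 1:7))
  expect_equal(n_sentences(render_narrative(fake)), 6)
  expect_false(grepl("Sentence 7", render_narrative(fake)))
})

test_that("missing findings are rejected by the concern rule", {
  s <- make_series(flat_day(3))
  rep <- metric_report(s, 3)
  expect_error(main_clinical_concern(rep, list()), "findings")
})
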