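# Hypnogram collapse, per-night summaries, trajectories, cohort filters.

test_that("collapse maps merge NREM stages and preserve wake and length", {
  hyp <- hypnogram(utc("2024-01-01 23:00:00"), c("W", "N1", "N2", "N3", "R"))
  h3 <- collapse_hypnogram(hyp, "three_class")
  expect_equal(as.character(h3$stage), c("W", "NREM", "NREM", "NREM", "R"))
  h2 <- collapse_hypnogram(hyp, "two_class")
  expect_equal(as.character(h2$stage),
               c("W", "SLEEP", "SLEEP", "SLEEP", "SLEEP"))

  allw <- hypnogram(utc("2024-01-01 23:00:00"), rep("W", 4))
  expect_equal(as.character(collapse_hypnogram(allw, "three_class")$stage),
               rep("W", 4))
  expect_equal(as.character(collapse_hypnogram(allw, "two_class")$stage),
               rep("W", 4))

  expect_error(collapse_stages("X", "two_class"), "unknown stage")
  expect_error(hypnogram(utc("2024-01-01 23:00:00"), "Q"), "unknown stage")
})

test_that("worked per-night summary matches hand arithmetic", {
  # 960-epoch window: 20 W before onset, then a mixture totalling a further
  # 100 W, 240 R and 600 NREM epochs
  set.seed(12)
  tail_stages <- sample(c(rep("W", 100), rep("R", 240),
                          rep("N2", 400), rep("N3", 200)))
  stages <- c(rep("W", 20), tail_stages)
  start <- utc("2024-01-01 23:00:00")
  hyp <- hypnogram(start, stages)
  win <- list(start = start, end = start + 960 * 30)
  s <- summarize_night(hyp, win)
  expect_equal(s$time_in_bed_h, 8)
  expect_equal(s$total_sleep_h, 7.0)
  expect_equal(s$sleep_efficiency_pct, 87.5)
  expect_equal(s$waso_min, 50)
  expect_equal(s$rem_h, 2.0)
  expect_equal(s$nrem_h, 5.0)
  expect_equal(s$rem_ratio_pct, 100 * 2 / 7, tolerance = 1e-9)
  expect_equal(s$nrem_ratio_pct, 100 * 5 / 7, tolerance = 1e-9)
  expect_equal(round(s$rem_ratio_pct, 2), 28.57)
  expect_equal(round(s$nrem_ratio_pct, 2), 71.43)

  # all-sleep window of 8 h
  asleep <- hypnogram(start, rep("N2", 960))
  s2 <- summarize_night(asleep, win)
  expect_equal(s2$sleep_efficiency_pct, 100)
  expect_equal(s2$waso_min, 0)

  # all-wake window
  awake <- hypnogram(start, rep("W", 960))
  s3 <- summarize_night(awake, win)
  expect_equal(s3$total_sleep_h, 0)
  expect_equal(s3$sleep_efficiency_pct, 0)
  expect_true(s3$no_sleep)
  expect_equal(s3$waso_min, 0)

  expect_error(summarize_night(hyp, list(start = start + 9 * 3600,
                                         end = start + 10 * 3600)),
               "no hypnogram epochs")
})

test_that("summaries agree with an epoch-counting oracle and hold invariants", {
  set.seed(31)
  start <- utc("2024-01-01 22:00:00")
  for (i in 1:200) {
    n <- sample(200:1000, 1)
    stages <- sample(STAGES5, n, replace = TRUE,
                     prob = c(0.15, 0.1, 0.35, 0.2, 0.2))
    hyp <- hypnogram(start, stages)
    win <- list(start = start, end = start + n * 30)
    s <- summarize_night(hyp, win)
    o <- oracle_night_summary(stages, n * 30 / 3600)
    expect_equal(s$total_sleep_h, o$tst, tolerance = 1e-12)
    expect_equal(s$sleep_efficiency_pct, o$eff, tolerance = 1e-9)
    expect_equal(s$waso_min, o$waso, tolerance = 1e-12)
    expect_equal(s$rem_h, o$rem, tolerance = 1e-12)
    expect_equal(s$nrem_h, o$nrem, tolerance = 1e-12)
    # invariants
    expect_equal(s$total_sleep_h, s$rem_h + s$nrem_h, tolerance = 1e-9)
    if (s$total_sleep_h > 0) {
      expect_equal(s$rem_ratio_pct + s$nrem_ratio_pct, 100, tolerance = 1e-9)
    }
    expect_true(s$sleep_efficiency_pct >= 0 && s$sleep_efficiency_pct <= 100)
    expect_lte(s$total_sleep_h, s$time_in_bed_h + 1e-12)
    # collapse commutes with total sleep
    s2 <- summarize_night(collapse_hypnogram(hyp, "two_class"), win)
    expect_equal(s2$total_sleep_h, s$total_sleep_h, tolerance = 1e-12)
  }
})

test_that("stage-probability trajectories reflect clock-time structure", {
  start <- utc("2024-01-01 23:00:00")
  hyp <- hypnogram(start, rep("N2", 960)) # 23:00 - 07:00 asleep
  tr <- stage_probability_trajectory(list(hyp), clock_bin_minutes = 60)
  n2 <- tr[tr$stage == "N2", ]
  covered <- n2$coverage > 0
  expect_true(all(n2$probability[covered] == 1))
  expect_equal(sum(covered), 8)
  # per-bin probabilities sum to 1 where covered
  sums <- aggregate(probability ~ bin_start_min, tr[tr$coverage > 0, ], sum)
  expect_true(all(abs(sums$probability - 1) < 1e-12))

  # two groups with bedtimes shifted by 60 min: sleep trajectories shifted
  early <- lapply(1:5, function(i) {
    simulate_hypnogram(default_stage_model(), 960, seed = i,
                       start_time = utc("2024-01-01 22:00:00"))
  })
  late <- lapply(1:5, function(i) {
    simulate_hypnogram(default_stage_model(), 960, seed = i,
                       start_time = utc("2024-01-01 23:00:00"))
  })
  tr2 <- stage_probability_trajectory(list(early = early, late = late),
                                      clock_bin_minutes = 30)
  # compare coverage (in-bed probability) profiles: the cross-correlation
  # peak should sit at a 60-min lag
  cov_e <- tr2$coverage[tr2$group == "early" & tr2$stage == "W"]
  cov_l <- tr2$coverage[tr2$group == "late" & tr2$stage == "W"]
  lags <- -4:4
  cc <- vapply(lags, function(l) {
    idx <- seq_along(cov_e)
    shifted <- ((idx - 1 + l) %% length(cov_e)) + 1
    sum(cov_e[shifted] * cov_l)
  }, numeric(1))
  # alignment peaks when one profile is shifted by 60 min (2 bins)
  expect_equal(abs(lags[which.max(cc)]), 2)
  expect_gt(max(cc), cc[lags == 0])
})

test_that("cohort filters enforce wear-day and weekday/weekend rules", {
  days <- as.Date("2024-03-04") + 0:6 # Monday..Sunday
  full <- data.frame(subject_id = "A", date = days, wear_hours = 24)
  r <- filter_cohort(full)
  expect_true(r$included)
  expect_equal(r$n_valid_days, 7)

  two <- data.frame(subject_id = "B", date = days,
                    wear_hours = c(23, 23, rep(10, 5)))
  r2 <- filter_cohort(two)
  expect_false(r2$included)
  expect_match(r2$reasons, "insufficient valid days")

  # 5 valid weekdays, no weekend
  wk <- data.frame(subject_id = "C", date = days,
                   wear_hours = c(rep(23, 5), 0, 0))
  r3 <- filter_cohort(wk)
  expect_false(r3$included)
  expect_match(r3$reasons, "weekend")
  r3b <- filter_cohort(wk, cohort_filter_config(require_weekday_and_weekend = FALSE))
  expect_true(r3b$included)

  # metadata exclusions
  md <- data.frame(subject_id = "A", shift_worker = TRUE,
                   dst_crossover = FALSE)
  r4 <- filter_cohort(full, metadata = md)
  expect_false(r4$included)
  expect_match(r4$reasons, "shift worker")
})
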