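# Preprocessing: reading, resampling/clipping, non-wear detection, QC,
# epoching.

make_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                      .local_envir = parent.frame())) {
  data.table::fwrite(df, path, dateTimeAs = "ISO")
  path
}

test_that("well-formed recording CSVs round-trip", {
  t0 <- utc("2024-01-01 00:00:00")
  p <- make_csv(data.frame(time = t0 + (0:2) / 30,
                           x = c(0.1, 0.2, 0.3), y = 0, z = 1))
  rec <- read_recording(p, "S1")
  expect_s3_class(rec, "raw_recording")
  expect_equal(nrow(rec$data), 3)
  expect_equal(rec$sample_rate, 30, tolerance = 0.01)
  expect_equal(rec$data[, "x"], c(0.1, 0.2, 0.3))
})

test_that("parse failures raise classed errors and mark recordings excluded", {
  t0 <- utc("2024-01-01 00:00:00")
  p_bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x,y,z", "2024-01-01T00:00:00Z,abc,0,1",
               "2024-01-01T00:00:01Z,0.1,0,1"), p_bad)
  expect_error(read_recording(p_bad), class = "actisleep_parse_error")

  p_empty <- withr::local_tempfile(fileext = ".csv")
  file.create(p_empty)
  expect_error(read_recording(p_empty), class = "actisleep_parse_error")

  p_cols <- make_csv(data.frame(time = t0 + (0:1) / 30, x = 0))
  expect_error(read_recording(p_cols), class = "actisleep_parse_error")

  p_mono <- make_csv(data.frame(time = t0 + c(0, 2, 1), x = 0, y = 0, z = 1))
  expect_error(read_recording(p_mono), class = "actisleep_parse_error")

  pp <- preprocess_recording(p_bad)
  expect_true(pp$qc$excluded)
  expect_true("unparseable" %in% pp$qc$reasons)
  expect_null(pp$epochs)
})

test_that("resampling interpolates onto the 30 Hz grid and clips at 3 g", {
  t0 <- utc("2024-01-01 00:00:00")
  # constant signal at 100 Hz for 10 s -> constant at 30 Hz, 300 samples
  rec <- raw_recording(matrix(0.5, 1000, 3), t0, 100)
  out <- resample_clip(rec)
  expect_equal(nrow(out$data), 300)
  expect_equal(out$sample_rate, 30)
  expect_true(all(abs(out$data - 0.5) < 1e-12))

  # linear ramp x(t) = t/10 over 10 s: interpolation is exact
  ramp <- (0:999) / 100 / 10
  rec2 <- raw_recording(cbind(ramp, 0, 1), t0, 100)
  out2 <- resample_clip(rec2)
  t_grid <- (seq_len(nrow(out2$data)) - 1) / 30
  expect_equal(out2$data[, 1], t_grid / 10, tolerance = 1e-9)

  # clipping
  rec3 <- raw_recording(cbind(c(5, -4, 2, 1), 0, 1), t0, 30)
  out3 <- resample_clip(rec3)
  expect_equal(unname(out3$data[1, 1]), 3)
  expect_equal(unname(out3$data[2, 1]), -3)
  expect_equal(unname(out3$data[3, 1]), 2)
})

test_that("resample_clip is idempotent on an already-conforming recording", {
  t0 <- utc("2024-01-01 00:00:00")
  set.seed(1)
  rec <- raw_recording(matrix(runif(900 * 3, -1, 1), ncol = 3), t0, 30)
  once <- resample_clip(rec)
  twice <- resample_clip(once)
  expect_equal(once$data, twice$data, tolerance = 1e-12)
  expect_equal(nrow(once$data), nrow(twice$data))
})

test_that("non-wear requires stillness strictly longer than 60 min", {
  t0 <- utc("2024-01-01 00:00:00")
  spe <- 900L
  active <- function(n) matrix(rnorm(n * spe * 3, 0, 0.05), ncol = 3)
  still <- function(n) matrix(rep(c(0, 0, 1), each = n * spe), ncol = 3)

  # 61 min of constant signal embedded in active signal -> one interval
  d61 <- rbind(active(20), still(122), active(20))
  r61 <- raw_recording(d61, t0, 30)
  nw <- detect_nonwear(r61)
  expect_equal(nrow(nw), 1)
  expect_equal(nw$start, t0 + 20 * 30)
  expect_equal(nw$end, t0 + (20 + 122) * 30)

  # 59 min -> nothing
  d59 <- rbind(active(20), still(118), active(20))
  expect_equal(nrow(detect_nonwear(raw_recording(d59, t0, 30))), 0)

  # 61 min but per-axis sd 20 mg -> nothing
  d_noisy <- rbind(active(20),
                   matrix(rnorm(122 * spe * 3, 0, 0.020), ncol = 3),
                   active(20))
  expect_equal(nrow(detect_nonwear(raw_recording(d_noisy, t0, 30))), 0)
})

test_that("non-wear detection agrees with a brute-force scan on random inputs", {
  t0 <- utc("2024-01-01 00:00:00")
  cfg <- preprocess_config(nonwear_min_minutes = 2) # short runs for testing
  set.seed(42)
  for (rep in 1:10) {
    n_ep <- 20L
    still_ep <- runif(n_ep) < 0.5
    data <- do.call(rbind, lapply(seq_len(n_ep), function(e) {
      if (still_ep[e]) matrix(rep(c(0, 0, 1), each = 900), ncol = 3)
      else matrix(rnorm(900 * 3, 0, 0.05), ncol = 3)
    }))
    rec <- raw_recording(data, t0, 30)
    got <- detect_nonwear(rec, cfg)
    # oracle: runs of still epochs strictly longer than 4 epochs
    r <- rle(still_ep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths > 4
    expect_equal(nrow(got), sum(keep))
    if (any(keep)) {
      expect_equal(as.numeric(got$start),
                   as.numeric(t0 + (starts[keep] - 1) * 30))
      expect_equal(as.numeric(got$end), as.numeric(t0 + ends[keep] * 30))
    }
  }
})

test_that("quality control flags unrealistic means and calibration error", {
  t0 <- utc("2024-01-01 00:00:00")
  # pure gravity: calibration error ~ 0, not excluded
  grav <- matrix(rep(c(0, 0, 1), each = 900 * 10), ncol = 3)
  qc <- quality_check(raw_recording(grav, t0, 30))
  expect_false(qc$excluded)
  expect_lt(qc$calibration_error_mg, 1e-9)

  # ENMO-style mean of 250 mg -> excluded
  hot <- matrix(rep(c(0, 0, 1.25), each = 900 * 10), ncol = 3)
  qc2 <- quality_check(raw_recording(hot, t0, 30))
  expect_gt(qc2$mean_acc_mg, 200)
  expect_true(qc2$excluded)
  expect_true("unrealistic high values" %in% qc2$reasons)

  # stationary recording with all norms 1.05 g -> calibration error 50 mg
  off <- matrix(rep(c(0, 0, 1.05), each = 900 * 10), ncol = 3)
  qc3 <- quality_check(raw_recording(off, t0, 30))
  expect_equal(qc3$calibration_error_mg, 50, tolerance = 1e-9)
  expect_true(qc3$excluded) # above the 30 mg default threshold
  expect_true("poorly calibrated" %in% qc3$reasons)

  # no stationary epochs: calibration undefined, recorded but not excluding
  set.seed(2)
  noisy <- matrix(rnorm(900 * 10 * 3, 0, 0.05), ncol = 3)
  qc4 <- quality_check(raw_recording(noisy, t0, 30))
  expect_true(is.na(qc4$calibration_error_mg))
  expect_false(qc4$excluded)
  expect_true("no stationary epochs for calibration" %in% qc4$reasons)
})

test_that("epoching produces 3 x 900 windows and drops partial tails", {
  t0 <- utc("2024-01-01 00:00:00")
  rec5 <- raw_recording(matrix(0.1, 9000, 3), t0, 30) # 5 min
  eps <- epochize(rec5)
  expect_equal(dim(eps$epochs), c(10, 3, 900))
  expect_equal(length(eps$epoch_start_times), 10)
  expect_equal(as.numeric(diff(eps$epoch_start_times)), rep(30, 9))

  rec_tail <- raw_recording(matrix(0.1, 9300, 3), t0, 30) # 5 min + 10 s
  expect_equal(dim(epochize(rec_tail)$epochs)[1], 10)

  # epoch count conservation on random lengths
  set.seed(3)
  for (n in sample(900:5000, 5)) {
    ep <- epochize(raw_recording(matrix(0, n, 3), t0, 30))
    k <- dim(ep$epochs)[1]
    expect_true(k * 900 <= n && n < (k + 1) * 900)
  }

  expect_warning(epochize(raw_recording(matrix(0, 100, 3), t0, 30)),
                 "zero epochs")
})

test_that("wear mask marks epochs intersecting non-wear intervals", {
  t0 <- utc("2024-01-01 00:00:00")
  set.seed(4)
  active <- matrix(rnorm(900 * 40 * 3, 0, 0.05), ncol = 3)
  still_idx <- (10 * 900 + 1):(30 * 900) # epochs 11..30 constant
  active[still_idx, ] <- matrix(rep(c(0, 0, 1), each = length(still_idx)),
                                ncol = 3)
  rec <- raw_recording(active, t0, 30)
  cfg <- preprocess_config(nonwear_min_minutes = 5)
  nw <- detect_nonwear(rec, cfg)
  eps <- epochize(rec, cfg, nonwear = nw)
  expect_equal(which(!eps$wear_mask), 11:30)
})
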