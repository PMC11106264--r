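# Minimum-wear-time simulation: random missing-data masking of complete
# weeks and intraclass correlation between sleep estimates from masked and
# complete data.

#' Masking scheme for wear-time simulation
#'
#' @param hours_retained_per_day hours of wear kept on each retained day
#'   (0 < hours <= 24).
#' @param days_retained number of days kept out of 7.
#' @return list of class `masking_scheme`.
#' @export
masking_scheme <- function(hours_retained_per_day, days_retained) {
  if (hours_retained_per_day <= 0 || hours_retained_per_day > 24) {
    stop("hours_retained_per_day must be in (0, 24]")
  }
  if (days_retained < 1 || days_retained > 7) {
    stop("days_retained must be in 1..7")
  }
  structure(list(hours_retained_per_day = hours_retained_per_day,
                 days_retained = days_retained),
            class = "masking_scheme")
}

#' Apply a random wear mask to a complete week
#'
#' Days to retain are drawn uniformly; within each retained day,
#' contiguous 1-h blocks are removed at random positions until exactly
#' `hours_retained_per_day` hours of wear remain. Non-retained days are
#' masked entirely. Deterministic under the seed.
#'
#' @param week logical wear vector over the 7-day epoch grid (length
#'   `7 * 2880`), or a list with elements `wear` (logical) and any per-epoch
#'   payload; only the mask is modified.
#' @param scheme a [masking_scheme()].
#' @param seed integer seed.
#' @return logical vector: the masked wear indicator (`TRUE` = retained).
#' @export
apply_wear_mask <- function(week, scheme, seed = 1L) {
  wear <- if (is.list(week)) week$wear else week
  epd <- 2880L # epochs per day
  if (length(wear) != 7L * epd) {
    stop("week must cover 7 days of 30-s epochs (", 7L * epd, " values)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- wear
  keep_days <- sort(sample.int(7L, scheme$days_retained))
  block <- 120L # 1-h blocks of 30-s epochs
  remove_epochs <- as.integer(round((24 - scheme$hours_retained_per_day) * 120))
  for (d in seq_len(7L)) {
    idx <- ((d - 1L) * epd + 1L):(d * epd)
    if (!(d %in% keep_days)) {
      out[idx] <- FALSE
      next
    }
    to_remove <- remove_epochs
    day_mask <- rep(TRUE, epd)
    guard <- 0L
    while (to_remove > 0L && guard < 10000L) {
      guard <- guard + 1L
      len <- min(block, to_remove)
      start <- sample.int(epd - len + 1L, 1L)
      seg <- start:(start + len - 1L)
      hit <- day_mask[seg]
      if (any(hit)) {
        day_mask[seg[hit]] <- FALSE
        to_remove <- to_remove - sum(hit)
      }
    }
    out[idx] <- out[idx] & day_mask
  }
  out
}

#' Two-way intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the standard ANOVA variance decomposition, for n
#' subjects each measured k times (here k = 2: masked and complete
#' estimates).
#'
#' @param pairs numeric matrix or data.frame, one row per subject, one
#'   column per measurement.
#' @return list of class `icc_result` with `icc`, `n_subjects`, `k`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `defined`.
#' @export
icc_two_way <- function(pairs) {
  m <- as.matrix(pairs)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("ICC needs >= 2 subjects and >= 2 measurements")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_error / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  defined <- abs(denom) > 1e-12
  icc <- if (defined) (msr - mse) / denom else NA_real_
  structure(
    list(icc = icc, n_subjects = n, k = k, ms_rows = msr, ms_cols = msc,
         ms_error = mse, defined = defined),
    class = "icc_result"
  )
}

#' Simulate a complete week of stage labels
#'
#' Label-level shortcut for wear-time simulation: seven noon-to-noon days
#' on the 30-s grid, ambulatory wake (`"A"`) outside bed and Markov-chain
#' stages inside, with full wear.
#'
#' @param stage_model a [stage_markov_model()].
#' @param seed integer seed.
#' @return list with `stages` (length `7 * 2880` character) and `wear`
#'   (logical, all `TRUE`).
#' @export
simulate_label_week <- function(stage_model = default_stage_model(),
                                seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  epd <- 2880L
  stages <- rep("A", 7L * epd)
  subj_bed_clock <- rnorm(1, parse_clock(stage_model$bedtime_mean),
                          stage_model$bedtime_subject_sd / 60)
  subj_tib_mean <- rnorm(1, stage_model$time_in_bed_mean,
                         stage_model$time_in_bed_subject_sd / 60)
  for (d in seq_len(7L)) {
    bed_clock <- rnorm(1, subj_bed_clock, stage_model$bedtime_sd / 60)
    tib_h <- max(4, rnorm(1, subj_tib_mean, stage_model$time_in_bed_sd / 60))
    # day grid runs noon-to-noon: offset of bedtime from noon
    off_ep <- as.integer(round(((bed_clock - 12) %% 24) * 120))
    n_bed <- as.integer(round(tib_h * 120))
    hyp_seed <- sample.int(.Machine$integer.max, 1L)
    hyp <- simulate_hypnogram(stage_model, n_bed, seed = hyp_seed)
    idx <- (d - 1L) * epd + off_ep + seq_len(n_bed)
    idx <- idx[idx <= 7L * epd]
    stages[idx] <- as.character(hyp$stage)[seq_along(idx)]
  }
  list(stages = stages, wear = rep(TRUE, 7L * epd))
}

# Weekly average overnight sleep duration (hours) from a week of per-epoch
# stage labels + wear mask: per noon-to-noon day, 30 s x worn non-wake
# epochs; weekly value = mean over days with any retained wear.
weekly_sleep_estimate <- function(stages, wear, days = NULL) {
  epd <- 2880L
  day_of <- rep(seq_len(7L), each = epd)
  asleep <- stages != "W" & stages != "A" & wear
  per_day <- rowsum(as.numeric(asleep), day_of)[, 1] / 120 # hours
  worn_day <- rowsum(as.numeric(wear), day_of)[, 1] > 0
  if (!any(worn_day)) return(NA_real_)
  mean(per_day[worn_day])
}

#' Grid search for minimum stable wear time
#'
#' For each (hours retained, days retained) grid cell, masks each
#' subject's complete week `reps` times, re-estimates the weekly average
#' sleep duration and computes the ICC against the complete-data estimate;
#' the minimal cell is the one with the least total retained hours among
#' cells whose mean ICC exceeds the threshold.
#'
#' @param cohort list of subject weeks; each element a list with `stages`
#'   (length `7*2880` labels, `"W"`/`"A"`/sleep stages) and `wear`
#'   (logical, all `TRUE` for complete weeks).
#' @param hours_grid,days_grid grid values.
#' @param icc_threshold stability threshold on the ICC.
#' @param reps mask replicates per cell.
#' @param seed integer seed.
#' @return list with `grid` (data.frame `hours`, `days`, `mean_icc`,
#'   `sd_icc`, `n_reps`), `minimal` (one-row data.frame or `NULL` when no
#'   cell meets the threshold), `monotone_in_hours` (logical flag).
#' @export
wear_grid_search <- function(cohort, hours_grid = c(16, 20, 22, 24),
                             days_grid = c(3, 5, 7), icc_threshold = 0.75,
                             reps = 5, seed = 1L) {
  full <- vapply(cohort, function(s) weekly_sleep_estimate(s$stages, s$wear),
                 numeric(1))
  rows <- list()
  for (h in hours_grid) {
    for (d in days_grid) {
      scheme <- masking_scheme(h, d)
      iccs <- numeric(reps)
      for (r in seq_len(reps)) {
        masked <- vapply(seq_along(cohort), function(i) {
          mseed <- seed + 7919L * r + 104729L * i + round(1000 * h) + d
          wear_m <- apply_wear_mask(cohort[[i]]$wear, scheme, seed = mseed)
          weekly_sleep_estimate(cohort[[i]]$stages, wear_m)
        }, numeric(1))
        iccs[r] <- icc_two_way(cbind(masked, full))$icc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hours = h, days = d, mean_icc = mean(iccs),
        sd_icc = if (reps > 1L) sd(iccs) else 0, n_reps = reps
      )
    }
  }
  grid <- do.call(rbind, rows)
  ok <- grid[grid$mean_icc > icc_threshold, , drop = FALSE]
  minimal <- if (nrow(ok) > 0L) {
    ok$total_hours <- ok$hours * ok$days
    ok[order(ok$total_hours, ok$hours), , drop = FALSE][1, c("hours", "days", "mean_icc")]
  } else {
    NULL
  }
  # on-average monotonicity of ICC in retained hours (per days level)
  mono <- all(vapply(split(grid, grid$days), function(g) {
    g <- g[order(g$hours), ]
    all(diff(g$mean_icc) >= -0.05)
  }, logical(1)))
  list(grid = grid, minimal = minimal, monotone_in_hours = mono)
}
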