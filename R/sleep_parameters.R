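# Per-night sleep parameters, face-validity trajectories and cohort
# inclusion filters.

#' Summarise a night of sleep
#'
#' Computes the per-night sleep parameters from a hypnogram restricted to a
#' time-in-bed window: total sleep duration (all non-wake epochs), sleep
#' efficiency (total sleep / window duration), WASO (all wake after the
#' first non-wake epoch up to the window end), REM and NREM durations and
#' their ratios of total sleep.
#'
#' @param hyp a five-class [hypnogram()] (or a prediction converted to
#'   one) covering the window.
#' @param window list or one-row data.frame with `start`, `end` (POSIXct);
#'   epochs with `start <= epoch_start < end` are used.
#' @return one-row data.frame of class `night_summary` with columns
#'   `time_in_bed_h`, `total_sleep_h`, `sleep_efficiency_pct`, `waso_min`,
#'   `rem_h`, `nrem_h`, `rem_ratio_pct`, `nrem_ratio_pct`, `sleep_onset`,
#'   `no_sleep` (flag: all-wake window, WASO reported as 0).
#' @export
summarize_night <- function(hyp, window) {
  stopifnot(inherits(hyp, "hypnogram"))
  sel <- hyp$epoch_start >= window$start & hyp$epoch_start < window$end
  if (!any(sel)) stop("window contains no hypnogram epochs")
  st <- as.character(hyp$stage[sel])
  n <- length(st)
  eph <- EPOCH_SECONDS / 3600 # epoch length in hours
  tib_h <- as.numeric(window$end - window$start, units = "hours")

  asleep <- st != "W"
  total_sleep_h <- sum(asleep) * eph
  rem_h <- sum(st == "R") * eph
  nrem_h <- sum(st %in% c("N1", "N2", "N3", "NREM", "SLEEP")) * eph
  no_sleep <- !any(asleep)
  onset_i <- match(TRUE, asleep)
  waso_min <- if (no_sleep) 0 else sum(st[onset_i:n] == "W") * EPOCH_SECONDS / 60
  out <- data.frame(
    time_in_bed_h = tib_h,
    total_sleep_h = total_sleep_h,
    sleep_efficiency_pct = 100 * total_sleep_h / tib_h,
    waso_min = waso_min,
    rem_h = rem_h,
    nrem_h = nrem_h,
    rem_ratio_pct = if (total_sleep_h > 0) 100 * rem_h / total_sleep_h else NA_real_,
    nrem_ratio_pct = if (total_sleep_h > 0) 100 * nrem_h / total_sleep_h else NA_real_,
    sleep_onset = if (no_sleep) utc(NA) else hyp$epoch_start[sel][onset_i],
    no_sleep = no_sleep
  )
  class(out) <- c("night_summary", "data.frame")
  out
}

#' Mean stage-probability trajectory by clock time
#'
#' For each clock-time bin, the fraction of person-epochs spent in each
#' stage among the epochs covered by the supplied hypnograms. Probabilities
#' are conditional on coverage (they sum to 1 over the stage alphabet
#' within each covered bin); the fraction of person-days covering the bin
#' is reported as `coverage`.
#'
#' @param hypnograms list of [hypnogram()] objects (one per night), or a
#'   named list of such lists to compare groups.
#' @param clock_bin_minutes bin width; must divide 24 h evenly.
#' @return data.frame with `group`, `bin_start_min` (minutes after
#'   midnight), `stage`, `probability`, `coverage`.
#' @export
stage_probability_trajectory <- function(hypnograms, clock_bin_minutes = 30) {
  if (1440 %% clock_bin_minutes != 0) {
    stop("clock_bin_minutes must divide 24 h evenly")
  }
  if (length(hypnograms) > 0L && inherits(hypnograms[[1]], "hypnogram")) {
    hypnograms <- list(all = hypnograms)
  }
  n_bins <- 1440 %/% clock_bin_minutes
  out <- list()
  for (g in names(hypnograms)) {
    hyps <- hypnograms[[g]]
    if (length(hyps) == 0L) next
    alphabet <- levels(hyps[[1]]$stage)
    counts <- matrix(0, n_bins, length(alphabet),
                     dimnames = list(NULL, alphabet))
    covered <- numeric(n_bins)
    for (h in hyps) {
      lt <- as.POSIXlt(h$epoch_start, tz = "UTC")
      mins <- lt$hour * 60 + lt$min + lt$sec / 60
      bin <- (floor(mins / clock_bin_minutes) %% n_bins) + 1L
      tab <- table(bin, h$stage)
      counts[as.integer(rownames(tab)), ] <-
        counts[as.integer(rownames(tab)), , drop = FALSE] + unclass(tab)
      covered[unique(bin)] <- covered[unique(bin)] + 1
    }
    tot <- rowSums(counts)
    for (s in alphabet) {
      out[[length(out) + 1L]] <- data.frame(
        group = g,
        bin_start_min = (seq_len(n_bins) - 1L) * clock_bin_minutes,
        stage = s,
        probability = ifelse(tot > 0, counts[, s] / tot, NA_real_),
        coverage = covered / length(hyps)
      )
    }
  }
  do.call(rbind, out)
}

#' Cohort filter configuration
#'
#' @param min_wear_hours_per_day minimum wear per calendar day for that day
#'   to count as valid (hours).
#' @param min_valid_days minimum number of valid days.
#' @param require_weekday_and_weekend require at least one valid weekday
#'   and one valid weekend day.
#' @param exclude_shift_workers,exclude_dst_crossover drop subjects whose
#'   metadata flags these conditions.
#' @return list of class `cohort_filter_config`.
#' @export
cohort_filter_config <- function(min_wear_hours_per_day = 22,
                                 min_valid_days = 3,
                                 require_weekday_and_weekend = TRUE,
                                 exclude_shift_workers = TRUE,
                                 exclude_dst_crossover = TRUE) {
  stopifnot(min_wear_hours_per_day > 0, min_valid_days > 0)
  structure(as.list(environment()), class = "cohort_filter_config")
}

#' Apply cohort inclusion filters
#'
#' A subject is included iff they have at least `min_valid_days` calendar
#' days with at least `min_wear_hours_per_day` hours of wear, and (when
#' required) at least one qualifying weekday and one weekend day
#' (Saturday/Sunday). Metadata flags can exclude shift workers and
#' daylight-saving crossovers.
#'
#' @param wear data.frame with columns `subject_id`, `date` (Date),
#'   `wear_hours`.
#' @param cfg a [cohort_filter_config()].
#' @param metadata optional data.frame with `subject_id` and logical
#'   columns `shift_worker`, `dst_crossover`.
#' @return data.frame with `subject_id`, `included`, `n_valid_days`,
#'   `reasons` (semicolon-joined; empty when included).
#' @export
filter_cohort <- function(wear, cfg = cohort_filter_config(), metadata = NULL) {
  stopifnot(all(c("subject_id", "date", "wear_hours") %in% names(wear)))
  ids <- unique(wear$subject_id)
  rows <- lapply(ids, function(sid) {
    w <- wear[wear$subject_id == sid, , drop = FALSE]
    valid <- w$wear_hours >= cfg$min_wear_hours_per_day
    wd <- as.POSIXlt(as.Date(w$date))$wday # 0 = Sunday, 6 = Saturday
    weekend <- wd %in% c(0L, 6L)
    reasons <- character()
    if (sum(valid) < cfg$min_valid_days) {
      reasons <- c(reasons, "insufficient valid days")
    }
    if (cfg$require_weekday_and_weekend &&
        (!any(valid & !weekend) || !any(valid & weekend))) {
      reasons <- c(reasons, "missing weekday or weekend day")
    }
    if (!is.null(metadata)) {
      md <- metadata[metadata$subject_id == sid, , drop = FALSE]
      if (nrow(md) == 1L) {
        if (cfg$exclude_shift_workers && isTRUE(md$shift_worker)) {
          reasons <- c(reasons, "shift worker")
        }
        if (cfg$exclude_dst_crossover && isTRUE(md$dst_crossover)) {
          reasons <- c(reasons, "daylight saving crossover")
        }
      }
    }
    data.frame(subject_id = sid, included = length(reasons) == 0L,
               n_valid_days = sum(valid),
               reasons = paste(reasons, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
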