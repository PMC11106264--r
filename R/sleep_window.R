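# Time-in-bed detection: random forest on per-epoch features, hidden
# Markov model smoothing of the forest probabilities, window merging and
# overnight-window selection. Also the random-forest stage baseline.

#' Label epochs as in-bed from a sleep diary
#'
#' An epoch is in bed when its start time lies inside any diary
#' `[fell_asleep, woke_up)` interval of its subject.
#'
#' @param epoch_times POSIXct epoch start times.
#' @param diary data.frame with columns `fell_asleep`, `woke_up` (and
#'   optionally `subject_id`).
#' @param subject_id optional subject to filter the diary by.
#' @return logical vector, one element per epoch.
#' @export
diary_epoch_labels <- function(epoch_times, diary, subject_id = NULL) {
  if (!is.null(subject_id) && "subject_id" %in% names(diary)) {
    diary <- diary[diary$subject_id == subject_id, , drop = FALSE]
  }
  in_bed <- rep(FALSE, length(epoch_times))
  for (i in seq_len(nrow(diary))) {
    in_bed[epoch_times >= diary$fell_asleep[i] &
             epoch_times < diary$woke_up[i]] <- TRUE
  }
  in_bed
}

#' Fit the time-in-bed detector
#'
#' A probability random forest is trained on epoch features against diary
#' derived in-bed labels; a 2-state HMM is estimated on top of it, with
#' transition probabilities from the empirical label sequence and a
#' discrete emission model over binned forest probabilities.
#'
#' @param features a [extract_features()] matrix (training epochs, in time
#'   order within each group).
#' @param in_bed logical vector of diary labels, one per feature row.
#' @param groups optional grouping vector (subject or subject-night);
#'   transitions are not counted across group boundaries.
#' @param seed integer seed for forest randomness.
#' @param num_trees forest size.
#' @param n_bins emission alphabet size (probability bins).
#' @return an object of class `sleep_window_model`.
#' @export
fit_window_model <- function(features, in_bed, groups = NULL, seed = 1L,
                             num_trees = 100, n_bins = 10) {
  stopifnot(length(in_bed) == nrow(features))
  if (length(unique(in_bed)) < 2L) {
    stop("in-bed labels contain a single class; cannot fit detector")
  }
  cols <- feature_columns(features)
  df <- as.data.frame(features)[, cols]
  df$.y <- factor(ifelse(in_bed, "in_bed", "out"), levels = c("out", "in_bed"))
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  # HMM transitions from the empirical label sequence
  if (is.null(groups)) groups <- rep(1L, length(in_bed))
  s <- as.integer(in_bed) + 1L # 1 = out, 2 = in_bed
  same <- groups[-1] == groups[-length(groups)]
  from <- s[-length(s)][same]
  to <- s[-1][same]
  trans <- matrix(1, 2, 2) # Laplace prior
  for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  trans <- trans / rowSums(trans)

  # discrete emissions: P(probability bin | state), Laplace-smoothed
  p_train <- forest$predictions[, "in_bed"]
  bin <- pmin(pmax(ceiling(p_train * n_bins), 1L), n_bins)
  emit <- matrix(1, 2, n_bins)
  for (i in seq_along(bin)) emit[s[i], bin[i]] <- emit[s[i], bin[i]] + 1
  emit <- emit / rowSums(emit)

  init <- c(out = mean(!in_bed), in_bed = mean(in_bed))
  structure(
    list(forest = forest, transition = trans, emission = emit, init = init,
         n_bins = n_bins, feature_names = cols, seed = seed),
    class = "sleep_window_model"
  )
}

#' Predict time-in-bed windows
#'
#' Forest per-epoch probabilities are decoded by Viterbi into a binary
#' out/in-bed path; maximal runs of the in-bed state become windows.
#'
#' @param model a [fit_window_model()].
#' @param features epoch features.
#' @param epoch_times POSIXct epoch start times (one per feature row).
#' @return data.frame of class `time_in_bed_windows` with columns `start`,
#'   `end`, `source` (`"detected"`).
#' @export
predict_time_in_bed <- function(model, features, epoch_times) {
  stopifnot(inherits(model, "sleep_window_model"))
  empty <- data.frame(start = utc(character()), end = utc(character()),
                      source = character())
  if (nrow(features) == 0L) return(empty)
  df <- as.data.frame(features)[, model$feature_names]
  p <- predict(model$forest, data = df, num.threads = 1,
               seed = model$seed)$predictions[, "in_bed"]
  bin <- pmin(pmax(ceiling(p * model$n_bins), 1L), model$n_bins)
  log_emit <- t(log(model$emission[, bin, drop = FALSE]))
  path <- viterbi(log(model$init), log(model$transition), log_emit)
  runs_to_windows(path == 2L, epoch_times)
}

# Convert a logical per-epoch state vector into [start, end) windows.
runs_to_windows <- function(state, epoch_times, source = "detected") {
  if (!any(state)) {
    return(data.frame(start = utc(character()), end = utc(character()),
                      source = character()))
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = epoch_times[starts[keep]],
    end = epoch_times[ends[keep]] + EPOCH_SECONDS,
    source = source
  )
}

#' Merge nearby time-in-bed windows
#'
#' Consecutive windows separated by at most `gap_minutes` are merged into
#' one window spanning both, applied transitively. Overlapping windows are
#' always merged.
#'
#' @param windows data.frame with `start`, `end` columns.
#' @param gap_minutes merge threshold in minutes.
#' @return merged windows (sorted by start, non-overlapping); merged rows
#'   get `source = "merged"`.
#' @export
merge_windows <- function(windows, gap_minutes = 60) {
  if (nrow(windows) == 0L) return(windows)
  w <- windows[order(windows$start), , drop = FALSE]
  out_start <- w$start[1]
  out_end <- w$end[1]
  out_src <- if ("source" %in% names(w)) w$source[1] else "detected"
  res <- list()
  for (i in seq_len(nrow(w))[-1]) {
    gap <- as.numeric(w$start[i] - out_end, units = "mins")
    if (gap <= gap_minutes) {
      out_end <- max(out_end, w$end[i])
      out_src <- "merged"
    } else {
      res[[length(res) + 1L]] <- data.frame(start = out_start, end = out_end,
                                            source = out_src)
      out_start <- w$start[i]
      out_end <- w$end[i]
      out_src <- if ("source" %in% names(w)) w$source[i] else "detected"
    }
  }
  res[[length(res) + 1L]] <- data.frame(start = out_start, end = out_end,
                                        source = out_src)
  do.call(rbind, res)
}

#' Select the overnight window per noon-to-noon interval
#'
#' Each window is assigned to the noon-to-noon interval containing its
#' midpoint; within each interval the longest window is selected (ties
#' break to the earliest start). The returned `night_date` is the calendar
#' date of the noon that opens the interval.
#'
#' @param windows merged windows (data.frame with `start`, `end`).
#' @param day_boundary_hour boundary hour of day (default 12 = noon).
#' @return data.frame with columns `night_date`, `start`, `end`,
#'   `duration_h`; at most one row per interval.
#' @export
select_overnight_window <- function(windows, day_boundary_hour = 12) {
  if (nrow(windows) == 0L) {
    return(data.frame(night_date = as.Date(character()),
                      start = utc(character()), end = utc(character()),
                      duration_h = numeric()))
  }
  mid <- windows$start + as.numeric(windows$end - windows$start, units = "secs") / 2
  mid_lt <- as.POSIXlt(mid, tz = "UTC")
  night_date <- as.Date(format(mid, "%Y-%m-%d", tz = "UTC")) -
    (mid_lt$hour + mid_lt$min / 60 < day_boundary_hour)
  dur <- as.numeric(windows$end - windows$start, units = "hours")
  df <- data.frame(night_date = night_date, start = windows$start,
                   end = windows$end, duration_h = dur)
  df <- df[order(df$night_date, -df$duration_h, df$start), , drop = FALSE]
  out <- df[!duplicated(df$night_date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random-forest sleep-stage baseline
#'
#' Five-class random forest on the hand-crafted epoch features, evaluated
#' by subject-wise k-fold cross-validation. Serves as the benchmark the
#' deep stager is compared against.
#'
#' @param features epoch features (one row per labelled epoch).
#' @param stages factor/character of true stage labels per epoch.
#' @param subjects subject identifier per epoch.
#' @param k number of folds.
#' @param seed integer seed (fold assignment and forests).
#' @param num_trees forest size.
#' @return factor of cross-validated predicted stages (levels
#'   `W, N1, N2, N3, R`), aligned with the input rows.
#' @export
rf_stage_baseline <- function(features, stages, subjects, k = 5, seed = 1L,
                              num_trees = 200) {
  stages <- factor(as.character(stages), levels = STAGES5)
  stopifnot(length(stages) == nrow(features), length(subjects) == nrow(features))
  folds <- make_folds(unique(subjects), k = k, seed = seed)
  fold_of <- folds$fold[match(subjects, folds$subject_id)]
  cols <- feature_columns(features)
  df <- as.data.frame(features)[, cols]
  pred <- factor(rep(NA_character_, nrow(df)), levels = STAGES5)
  for (f in sort(unique(fold_of))) {
    tr <- fold_of != f
    if (length(unique(droplevels(stages[tr]))) < 2L) {
      stop("training fold contains a single stage class")
    }
    dtr <- df[tr, , drop = FALSE]
    dtr$.y <- droplevels(stages[tr])
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dtr,
                          num.trees = num_trees, seed = seed + f,
                          num.threads = 1)
    pred[!tr] <- as.character(predict(fit, data = df[!tr, , drop = FALSE],
                                      num.threads = 1,
                                      seed = seed + f)$predictions)
  }
  pred
}
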