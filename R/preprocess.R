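# Raw-signal preprocessing: resampling, clipping, epoching, non-wear
# detection and quality exclusions.

#' Preprocessing configuration
#'
#' Houses the preprocessing constants: resample to 30 Hz, clip to +/-3 g,
#' 30-s epochs, non-wear = stationary (per-axis SD < 13 mg) runs longer
#' than 60 min, exclusion of recordings with ENMO-style mean above 200 mg
#' or calibration error above `calibration_error_mg`.
#'
#' @param target_rate resampling target in Hz.
#' @param clip_g clipping bound in g.
#' @param epoch_seconds epoch length in seconds.
#' @param nonwear_sd_mg stationarity threshold on each axis SD (mg).
#' @param nonwear_min_minutes minimum non-wear run length (strictly greater
#'   than, in minutes).
#' @param unrealistic_mean_mg exclusion threshold on the recording-level
#'   ENMO-style mean (mg).
#' @param calibration_error_mg exclusion threshold on the stationary-sphere
#'   calibration error (mg).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 30, clip_g = 3, epoch_seconds = 30,
                              nonwear_sd_mg = 13, nonwear_min_minutes = 60,
                              unrealistic_mean_mg = 200,
                              calibration_error_mg = 30) {
  vals <- as.list(environment())
  if (any(unlist(vals) <= 0)) stop("all preprocessing constants must be positive")
  structure(vals, class = "preprocess_config")
}

#' Read a recording CSV
#'
#' Expects columns `time` (ISO-8601, UTC), `x`, `y`, `z` (units g). Parse
#' problems (missing columns, non-numeric values, non-monotone timestamps,
#' empty files) raise a classed error (`actisleep_parse_error`);
#' [preprocess_recording()] converts these into a QC exclusion.
#'
#' @param path CSV file path.
#' @param subject_id optional subject identifier.
#' @return a [raw_recording()]; sample rate is inferred from the median
#'   timestamp increment.
#' @export
read_recording <- function(path, subject_id = NA_character_) {
  parse_fail <- function(msg) {
    stop(structure(
      class = c("actisleep_parse_error", "error", "condition"),
      list(message = paste0(msg, " [", path, "]"), call = sys.call(-1))
    ))
  }
  if (!file.exists(path)) parse_fail("file does not exist")
  dt <- tryCatch(
    suppressWarnings(data.table::fread(path, showProgress = FALSE)),
    error = function(e) parse_fail(paste("unreadable CSV:", conditionMessage(e)))
  )
  if (nrow(dt) == 0L) parse_fail("empty file")
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(dt))) {
    parse_fail(paste("missing column(s):",
                     paste(setdiff(need, names(dt)), collapse = ", ")))
  }
  tm <- dt$time
  if (!inherits(tm, "POSIXct")) {
    tm <- suppressWarnings(as.POSIXct(as.character(tm),
                                      format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  }
  if (anyNA(tm)) parse_fail("unparseable timestamps")
  xyz <- suppressWarnings(cbind(as.numeric(dt$x), as.numeric(dt$y),
                                as.numeric(dt$z)))
  if (anyNA(xyz)) parse_fail("unparseable (non-numeric) sample values")
  d <- diff(as.numeric(tm))
  if (length(d) > 0L && any(d <= 0)) parse_fail("non-monotone timestamps")
  # infer the rate from the total span: robust to sub-sample timestamp
  # rounding (e.g. millisecond-precision CSVs at 30 Hz)
  rate <- if (length(d) > 0L) {
    (length(tm) - 1) / (as.numeric(tm[length(tm)]) - as.numeric(tm[1]))
  } else {
    30
  }
  raw_recording(xyz, tm[1], rate, subject_id)
}

#' Resample to the target rate and clip
#'
#' Linear interpolation of each axis onto the uniform target-rate grid
#' anchored at the recording start time, followed by clipping to
#' `[-clip_g, +clip_g]`.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return a [raw_recording()] at `cfg$target_rate`.
#' @export
resample_clip <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  n_in <- nrow(rec$data)
  dur <- (n_in - 1) / rec$sample_rate
  n_out <- floor(dur * cfg$target_rate) + 1L
  if (n_in < 2L || n_out < 1L) stop("recording too short to resample")
  t_in <- (seq_len(n_in) - 1) / rec$sample_rate
  t_out <- (seq_len(n_out) - 1) / cfg$target_rate
  out <- vapply(1:3, function(a) {
    approx(t_in, rec$data[, a], xout = t_out, method = "linear", rule = 2)$y
  }, numeric(n_out))
  out <- pmin(pmax(out, -cfg$clip_g), cfg$clip_g)
  raw_recording(matrix(out, ncol = 3), rec$start_time, cfg$target_rate,
                rec$subject_id)
}

# Per-epoch per-axis SDs on the 30-s grid. Returns list(sd = n_ep x 3 [mg],
# epoch_start = POSIXct, spe = samples per epoch).
epoch_axis_sd <- function(rec, cfg) {
  spe <- as.integer(round(rec$sample_rate * cfg$epoch_seconds))
  n_ep <- nrow(rec$data) %/% spe
  if (n_ep < 1L) {
    return(list(sd = matrix(numeric(0), 0, 3), epoch_start = rec$start_time[0],
                spe = spe, n_ep = 0L))
  }
  idx <- seq_len(n_ep * spe)
  grp <- rep(seq_len(n_ep), each = spe)
  sds <- vapply(1:3, function(a) {
    x <- rec$data[idx, a]
    m <- rowsum(x, grp) / spe
    m2 <- rowsum(x * x, grp) / spe
    sqrt(pmax(m2 - m[, 1]^2, 0) * spe / (spe - 1))[, 1] * 1000
  }, numeric(n_ep))
  list(sd = matrix(sds, ncol = 3),
       epoch_start = rec$start_time + (seq_len(n_ep) - 1) * cfg$epoch_seconds,
       spe = spe, n_ep = n_ep)
}

#' Detect non-wear intervals
#'
#' An interval is non-wear iff every axis's SD, computed per 30-s epoch, is
#' below `nonwear_sd_mg` for a contiguous run strictly longer than
#' `nonwear_min_minutes`. Intervals are reported as half-open
#' `[start, end)` timestamps.
#'
#' @param rec a [raw_recording()] at the target rate.
#' @param cfg a [preprocess_config()].
#' @return data.frame with columns `start`, `end` (possibly zero rows).
#' @export
detect_nonwear <- function(rec, cfg = preprocess_config()) {
  es <- epoch_axis_sd(rec, cfg)
  out <- data.frame(start = es$epoch_start[0], end = es$epoch_start[0])
  if (es$n_ep == 0L) return(out)
  still <- rowSums(es$sd < cfg$nonwear_sd_mg) == 3L
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_epochs <- cfg$nonwear_min_minutes * 60 / cfg$epoch_seconds
  keep <- r$values & (r$lengths > min_epochs)
  if (!any(keep)) return(out)
  data.frame(
    start = es$epoch_start[starts[keep]],
    end = es$epoch_start[1] + ends[keep] * cfg$epoch_seconds
  )
}

#' Quality-check a recording
#'
#' Computes the ENMO-style mean (vector magnitude minus 1 g, floored at 0)
#' and a stationary-sphere calibration error (mean absolute deviation of
#' the vector norm from 1 g over stationary epochs). A recording is
#' excluded when its ENMO-style mean exceeds `unrealistic_mean_mg`, when
#' its calibration error exceeds `calibration_error_mg`, or when parsing
#' failed upstream.
#'
#' @param rec a [raw_recording()] at the target rate, or `NULL` when
#'   parsing failed.
#' @param cfg a [preprocess_config()].
#' @param parse_ok set to `FALSE` by [preprocess_recording()] on parse
#'   failure.
#' @return a list of class `qc_report` with fields `parse_ok`,
#'   `mean_acc_mg`, `calibration_error_mg`, `excluded`, `reasons`.
#' @export
quality_check <- function(rec, cfg = preprocess_config(), parse_ok = TRUE) {
  reasons <- character()
  mean_acc <- NA_real_
  calib <- NA_real_
  if (!parse_ok || is.null(rec)) {
    reasons <- c(reasons, "unparseable")
  } else {
    vm <- sqrt(rowSums(rec$data^2))
    mean_acc <- mean(pmax(vm - 1, 0)) * 1000
    if (mean_acc > cfg$unrealistic_mean_mg) {
      reasons <- c(reasons, "unrealistic high values")
    }
    es <- epoch_axis_sd(rec, cfg)
    still <- if (es$n_ep > 0L) rowSums(es$sd < cfg$nonwear_sd_mg) == 3L else logical(0)
    if (!any(still)) {
      # calibration cannot be assessed without stationary data; recorded but
      # not an exclusion on its own
      reasons <- c(reasons, "no stationary epochs for calibration")
    } else {
      idx_ep <- which(still)
      sel <- as.vector(outer(seq_len(es$spe), (idx_ep - 1L) * es$spe, `+`))
      calib <- mean(abs(sqrt(rowSums(rec$data[sel, , drop = FALSE]^2)) - 1)) * 1000
      if (calib > cfg$calibration_error_mg) {
        reasons <- c(reasons, "poorly calibrated")
      }
    }
  }
  excluded <- any(reasons %in% c("unparseable", "unrealistic high values",
                                 "poorly calibrated"))
  structure(
    list(parse_ok = parse_ok, mean_acc_mg = mean_acc,
         calibration_error_mg = calib, excluded = excluded,
         reasons = reasons),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> parse_ok=%s mean_acc=%.1f mg calib_err=%.1f mg excluded=%s%s\n",
    x$parse_ok, x$mean_acc_mg, x$calibration_error_mg, x$excluded,
    if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = "; "), "]") else ""
  ))
  invisible(x)
}

#' Cut a recording into 30-s epoch windows
#'
#' @param rec a [raw_recording()] at the target rate.
#' @param cfg a [preprocess_config()].
#' @param nonwear optional data.frame of non-wear intervals (from
#'   [detect_nonwear()]); epochs intersecting any interval get
#'   `wear_mask = FALSE`.
#' @return an object of class `epoch_tensor`: list with `epochs` (array
#'   `n_epochs x 3 x samples_per_epoch`), `epoch_start_times`, `wear_mask`,
#'   `subject_id`. Trailing partial windows are dropped.
#' @export
epochize <- function(rec, cfg = preprocess_config(), nonwear = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  spe <- as.integer(round(rec$sample_rate * cfg$epoch_seconds))
  n_ep <- nrow(rec$data) %/% spe
  if (n_ep < 1L) {
    warning("recording shorter than one epoch; zero epochs returned")
  }
  arr <- array(0, dim = c(n_ep, 3L, spe))
  if (n_ep > 0L) {
    # samples are row-major in time: reshape each axis to spe x n_ep
    for (a in 1:3) {
      arr[, a, ] <- t(matrix(rec$data[seq_len(n_ep * spe), a], nrow = spe))
    }
  }
  starts <- rec$start_time + (seq_len(n_ep) - 1) * cfg$epoch_seconds
  wear <- rep(TRUE, n_ep)
  if (!is.null(nonwear) && nrow(nonwear) > 0L && n_ep > 0L) {
    ep_end <- starts + cfg$epoch_seconds
    for (i in seq_len(nrow(nonwear))) {
      wear[starts < nonwear$end[i] & ep_end > nonwear$start[i]] <- FALSE
    }
  }
  structure(
    list(epochs = arr, epoch_start_times = starts, wear_mask = wear,
         subject_id = rec$subject_id),
    class = "epoch_tensor"
  )
}

#' @export
print.epoch_tensor <- function(x, ...) {
  cat(sprintf("<epoch_tensor> %d epochs x 3 axes x %d samples (%d non-wear)\n",
              dim(x$epochs)[1], dim(x$epochs)[3], sum(!x$wear_mask)))
  invisible(x)
}

#' Full preprocessing of one recording file or object
#'
#' Read (if given a path), resample and clip, quality-check, detect
#' non-wear, and epochize. Parse failures do not raise: they are returned
#' as an excluded [quality_check()] report.
#'
#' @param x path to a recording CSV or a [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @param subject_id optional subject identifier (when `x` is a path).
#' @return list with `epochs` (an `epoch_tensor` or `NULL`), `qc`
#'   (`qc_report`), `nonwear` (data.frame), `recording` (resampled
#'   [raw_recording()] or `NULL`).
#' @export
preprocess_recording <- function(x, cfg = preprocess_config(),
                                 subject_id = NA_character_) {
  rec <- NULL
  parse_ok <- TRUE
  if (is.character(x)) {
    rec <- tryCatch(read_recording(x, subject_id),
                    actisleep_parse_error = function(e) NULL)
    parse_ok <- !is.null(rec)
  } else {
    stopifnot(inherits(x, "raw_recording"))
    rec <- x
  }
  if (!parse_ok) {
    return(list(epochs = NULL, qc = quality_check(NULL, cfg, parse_ok = FALSE),
                nonwear = NULL, recording = NULL))
  }
  rec <- resample_clip(rec, cfg)
  qc <- quality_check(rec, cfg, parse_ok = TRUE)
  nw <- detect_nonwear(rec, cfg)
  eps <- epochize(rec, cfg, nonwear = nw)
  list(epochs = eps, qc = qc, nonwear = nw, recording = rec)
}
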