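#' Construct a raw accelerometer recording
#'
#' A continuous tri-axial acceleration time series in gravitational units
#' (g) with a start time and nominal sample rate. Samples are assumed
#' uniformly spaced at `sample_rate`.
#'
#' @param data numeric matrix with columns `x`, `y`, `z` (units g).
#' @param start_time `POSIXct` (UTC) time of the first sample.
#' @param sample_rate sampling frequency in Hz.
#' @param subject_id optional subject identifier.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(data, start_time, sample_rate, subject_id = NA_character_) {
  data <- as.matrix(data)
  if (ncol(data) != 3L) stop("recording data must have 3 columns (x, y, z)")
  if (nrow(data) < 1L) stop("recording has no samples")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  colnames(data) <- c("x", "y", "z")
  attr(start_time, "tzone") <- "UTC"
  structure(
    list(
      subject_id = subject_id,
      start_time = start_time,
      sample_rate = sample_rate,
      data = data
    ),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$sample_rate
  cat(sprintf(
    "<raw_recording> subject=%s, %d samples @ %g Hz (%.1f min) from %s UTC\n",
    x$subject_id, nrow(x$data), x$sample_rate, dur / 60,
    format(x$start_time, "%Y-%m-%d %H:%M:%S")
  ))
  invisible(x)
}

# Sample times of a recording (POSIXct, UTC).
recording_times <- function(rec) {
  rec$start_time + (seq_len(nrow(rec$data)) - 1) / rec$sample_rate
}

recording_duration <- function(rec) nrow(rec$data) / rec$sample_rate

#' Write / read a recording CSV
#'
#' The on-disk interchange format is a CSV with columns `time` (ISO-8601,
#' UTC), `x`, `y`, `z` (units g).
#'
#' @param rec a [raw_recording()].
#' @param path file path.
#' @return `write_recording_csv` returns `path` invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  dt <- data.table::data.table(
    time = recording_times(rec),
    x = rec$data[, 1], y = rec$data[, 2], z = rec$data[, 3]
  )
  data.table::fwrite(dt, path, dateTimeAs = "ISO")
  invisible(path)
}
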