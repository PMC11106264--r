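#' @useDynLib actisleep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median predict quantile rnorm runif sd setNames
#'   rpois aggregate
#' @importFrom utils head tail
NULL

# AASM five-stage alphabet, fixed ordering used throughout.
STAGES5 <- c("W", "N1", "N2", "N3", "R")
STAGES3 <- c("W", "NREM", "R")
STAGES2 <- c("W", "SLEEP")

EPOCH_SECONDS <- 30L

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of AASM sleep-stage labels for a
#' recording, on a contiguous 30-second grid.
#'
#' @param epoch_start `POSIXct` (UTC) start time of the first epoch, or a
#'   vector of per-epoch start times on a contiguous 30-s grid.
#' @param stages character vector of stage labels in
#'   `c("W","N1","N2","N3","R")` (or a collapsed alphabet, see
#'   [collapse_hypnogram()]).
#' @param scheme label alphabet: `"five_class"`, `"three_class"` or
#'   `"two_class"`.
#' @return an object of class `hypnogram`: a `data.frame` with columns
#'   `epoch_start` (POSIXct, UTC) and `stage` (factor), with attribute
#'   `scheme`.
#' @export
hypnogram <- function(epoch_start, stages, scheme = "five_class") {
  alphabet <- switch(scheme,
    five_class = STAGES5,
    three_class = STAGES3,
    two_class = STAGES2,
    stop("unknown scheme: ", scheme)
  )
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), alphabet)
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  n <- length(stages)
  if (n < 1L) stop("hypnogram needs at least one epoch")
  if (length(epoch_start) == 1L) {
    epoch_start <- epoch_start + EPOCH_SECONDS * (seq_len(n) - 1L)
  }
  if (length(epoch_start) != n) {
    stop("epoch_start and stages lengths differ")
  }
  if (n > 1L) {
    d <- as.numeric(diff(as.numeric(epoch_start)))
    if (any(abs(d - EPOCH_SECONDS) > 1e-6)) {
      stop("epoch_start times must lie on a contiguous 30-s grid")
    }
  }
  attr(epoch_start, "tzone") <- "UTC"
  out <- data.frame(
    epoch_start = epoch_start,
    stage = factor(stages, levels = alphabet)
  )
  class(out) <- c("hypnogram", "data.frame")
  attr(out, "scheme") <- scheme
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram> %d epochs (%s), %s to %s UTC\n",
    nrow(x), attr(x, "scheme"),
    format(x$epoch_start[1], "%Y-%m-%d %H:%M:%S"),
    format(x$epoch_start[nrow(x)] + EPOCH_SECONDS, "%Y-%m-%d %H:%M:%S")
  ))
  print(table(x$stage))
  invisible(x)
}

#' Collapse a five-class hypnogram to three or two classes
#'
#' The three-class scheme merges the NREM stages into one class
#' (wake / NREM / REM); the two-class scheme additionally merges REM and
#' NREM into a single sleep class (wake / sleep). Wake is never remapped
#' and sequence length is preserved.
#'
#' @param hyp a five-class [hypnogram()].
#' @param scheme `"three_class"` or `"two_class"`.
#' @return a [hypnogram()] in the collapsed alphabet.
#' @export
collapse_hypnogram <- function(hyp, scheme = c("three_class", "two_class")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(hyp, "hypnogram"))
  if (!identical(attr(hyp, "scheme"), "five_class")) {
    stop("collapse_hypnogram() expects a five-class hypnogram")
  }
  labels <- as.character(hyp$stage)
  if (anyNA(labels)) stop("hypnogram contains missing stage labels")
  out <- collapse_stages(labels, scheme)
  hypnogram(hyp$epoch_start, out, scheme = scheme)
}

#' Collapse stage labels to a coarser scheme
#'
#' Label-level version of [collapse_hypnogram()] for arbitrary label
#' vectors (e.g. model predictions).
#'
#' @param labels character/factor vector of five-class stage labels.
#' @param scheme `"three_class"` or `"two_class"`.
#' @return character vector in the collapsed alphabet.
#' @export
collapse_stages <- function(labels, scheme = c("three_class", "two_class")) {
  scheme <- match.arg(scheme)
  map <- if (scheme == "three_class") {
    c(W = "W", N1 = "NREM", N2 = "NREM", N3 = "NREM", R = "R")
  } else {
    c(W = "W", N1 = "SLEEP", N2 = "SLEEP", N3 = "SLEEP", R = "SLEEP")
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(map))
  if (length(bad) > 0L) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  unname(map[labels])
}

# Parse "HH:MM" clock strings to fractional hours.
parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) + as.numeric(parts[2]) / 60
}

utc <- function(x) as.POSIXct(x, tz = "UTC")
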