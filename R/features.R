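# Hand-crafted per-epoch spatiotemporal features, the input of the
# time-in-bed detector and of the random-forest stage baseline.
#
# The set follows standard actigraphy practice: movement intensity (ENMO),
# per-axis moments and ranges, posture (arm angle of the z axis against the
# horizontal plane) and its dynamics, in-band (0.3-3 Hz) spectral power
# fraction, and a rolling 5-min median of ENMO for slow context.

#' Extract per-epoch features
#'
#' @param epochs an `epoch_tensor` from [epochize()].
#' @param wear_only drop non-wear epochs (default `TRUE`).
#' @return an object of class `feature_matrix`: a data.frame with one row
#'   per (wear) epoch, columns `epoch_start` plus the feature columns, and
#'   attribute `feature_names`.
#' @export
extract_features <- function(epochs, wear_only = TRUE) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  n_ep <- dim(epochs$epochs)[1]
  spe <- dim(epochs$epochs)[3]
  keep <- if (wear_only) which(epochs$wear_mask) else seq_len(n_ep)
  feat_names <- c(
    "enmo_mean", "x_mean", "y_mean", "z_mean", "x_sd", "y_sd", "z_sd",
    "x_range", "y_range", "z_range", "vm_sd", "angle_mean", "angle_sd",
    "angle_change", "power_ratio", "enmo_roll_med"
  )
  if (length(keep) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(feat_names)))
    names(out) <- feat_names
    out <- cbind(data.frame(epoch_start = epochs$epoch_start_times[0]), out)
    class(out) <- c("feature_matrix", "data.frame")
    attr(out, "feature_names") <- feat_names
    return(out)
  }

  n <- length(keep)
  # axis matrices: spe x n
  X <- t(epochs$epochs[keep, 1, , drop = FALSE][, 1, ])
  Y <- t(epochs$epochs[keep, 2, , drop = FALSE][, 1, ])
  Z <- t(epochs$epochs[keep, 3, , drop = FALSE][, 1, ])
  if (n == 1L) { X <- matrix(X, ncol = 1); Y <- matrix(Y, ncol = 1); Z <- matrix(Z, ncol = 1) }

  vm <- sqrt(X^2 + Y^2 + Z^2)
  enmo <- pmax(vm - 1, 0)
  colsd <- function(M) {
    m <- colMeans(M)
    sqrt(pmax(colMeans(M^2) - m^2, 0) * spe / (spe - 1))
  }
  ang <- atan2(Z, sqrt(X^2 + Y^2)) * 180 / pi
  angle_mean <- colMeans(ang)
  angle_change <- c(0, abs(diff(angle_mean)))

  # in-band power fraction of the vector magnitude, 0.3-3 Hz
  fs <- spe / EPOCH_SECONDS
  vc <- sweep(vm, 2, colMeans(vm)) # remove DC
  sp <- abs(stats::mvfft(vc))^2
  freqs <- (seq_len(spe) - 1) * fs / spe
  half <- freqs > 0 & freqs <= fs / 2
  band <- half & freqs >= 0.3 & freqs <= 3
  tot <- colSums(sp[half, , drop = FALSE])
  pr <- ifelse(tot > 0, colSums(sp[band, , drop = FALSE]) / tot, 0)

  enmo_mean <- colMeans(enmo) * 1000
  k <- min(11L, if (n %% 2L == 1L) n else n - 1L)
  roll_med <- if (n >= 3L && k >= 3L) stats::runmed(enmo_mean, k) else enmo_mean

  out <- data.frame(
    epoch_start = epochs$epoch_start_times[keep],
    enmo_mean = enmo_mean,
    x_mean = colMeans(X), y_mean = colMeans(Y), z_mean = colMeans(Z),
    x_sd = colsd(X) * 1000, y_sd = colsd(Y) * 1000, z_sd = colsd(Z) * 1000,
    x_range = apply(X, 2, function(v) diff(range(v))) * 1000,
    y_range = apply(Y, 2, function(v) diff(range(v))) * 1000,
    z_range = apply(Z, 2, function(v) diff(range(v))) * 1000,
    vm_sd = colsd(vm) * 1000,
    angle_mean = angle_mean,
    angle_sd = apply(ang, 2, sd),
    angle_change = angle_change,
    power_ratio = pr,
    enmo_roll_med = as.numeric(roll_med)
  )
  class(out) <- c("feature_matrix", "data.frame")
  attr(out, "feature_names") <- feat_names
  out
}

feature_columns <- function(features) {
  attr(features, "feature_names") %||%
    setdiff(names(features), c("epoch_start", "subject_id", "night"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
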