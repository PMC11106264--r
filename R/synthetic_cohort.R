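# Synthetic multi-night accelerometer cohorts with ground-truth hypnograms.
#
# The generator produces the three ingredients every downstream stage needs:
# (1) per-night stage sequences from a first-order Markov chain over the
#     AASM alphabet (geometric stage dwell times),
# (2) a tri-axial 30 Hz-or-higher signal built as a slowly varying unit-norm
#     gravity vector plus stage-dependent movement bursts and white noise,
# (3) sleep diaries (truth +/- uniform self-report noise) and optional
#     injected non-wear gaps.
# Movement energy is ordered wake >> REM > N1 > N2 > N3 so that sleep/wake
# is strongly separable while REM vs NREM is only weakly separable.

#' Stage-transition model for synthetic hypnograms
#'
#' First-order Markov chain over the five AASM stages at 30-s epoch
#' resolution, plus the bed-timing distribution used when assembling
#' multi-night subjects.
#'
#' @param transition_matrix 5x5 row-stochastic matrix (rows/cols ordered
#'   W, N1, N2, N3, R): per-epoch stage transition probabilities.
#' @param initial_distribution length-5 probability vector for the first
#'   in-bed epoch.
#' @param bedtime_mean mean bedtime as a `"HH:MM"` clock string.
#' @param bedtime_sd night-to-night bedtime SD in minutes.
#' @param time_in_bed_mean mean time in bed in hours.
#' @param time_in_bed_sd night-to-night time-in-bed SD in minutes.
#' @param bedtime_subject_sd,time_in_bed_subject_sd between-subject SDs (in
#'   minutes) of the subject-level mean bedtime and time in bed; population
#'   heterogeneity of habitual sleep timing and duration.
#' @return an object of class `stage_markov_model`.
#' @export
stage_markov_model <- function(transition_matrix,
                               initial_distribution,
                               bedtime_mean = "23:00",
                               bedtime_sd = 30,
                               time_in_bed_mean = 8,
                               time_in_bed_sd = 30,
                               bedtime_subject_sd = 45,
                               time_in_bed_subject_sd = 45) {
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(5L, 5L))) {
    stop("transition_matrix must be 5x5")
  }
  if (any(transition_matrix < 0) || any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition_matrix rows must be non-negative and sum to 1")
  }
  if (length(initial_distribution) != 5L || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9) {
    stop("initial_distribution must be a length-5 probability vector")
  }
  if (time_in_bed_mean <= 0) stop("time_in_bed_mean must be > 0")
  dimnames(transition_matrix) <- list(STAGES5, STAGES5)
  structure(
    list(
      transition_matrix = transition_matrix,
      initial_distribution = setNames(as.numeric(initial_distribution), STAGES5),
      bedtime_mean = bedtime_mean,
      bedtime_sd = bedtime_sd,
      time_in_bed_mean = time_in_bed_mean,
      time_in_bed_sd = time_in_bed_sd,
      bedtime_subject_sd = bedtime_subject_sd,
      time_in_bed_subject_sd = time_in_bed_subject_sd
    ),
    class = "stage_markov_model"
  )
}

#' Default stage-transition preset
#'
#' Dwell parameters give realistic mean bout lengths at 30-s resolution
#' (e.g. sustained N2/N3/REM bouts, brief N1) and an overall architecture
#' dominated by NREM with roughly a fifth of sleep in REM.
#'
#' @return a [stage_markov_model()].
#' @export
default_stage_model <- function() {
  P <- rbind(
    W  = c(0.900, 0.085, 0.010, 0.000, 0.005),
    N1 = c(0.050, 0.600, 0.330, 0.000, 0.020),
    N2 = c(0.010, 0.015, 0.900, 0.050, 0.025),
    N3 = c(0.005, 0.000, 0.070, 0.925, 0.000),
    R  = c(0.020, 0.025, 0.025, 0.000, 0.930)
  )
  stage_markov_model(P, initial_distribution = c(0.9, 0.1, 0, 0, 0))
}

#' Stationary distribution of a stage-transition model
#'
#' Computed from the left eigenvector of the transition matrix with unit
#' eigenvalue.
#'
#' @param model a [stage_markov_model()].
#' @return named length-5 probability vector.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "stage_markov_model"))
  e <- eigen(t(model$transition_matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  setNames(v / sum(v), STAGES5)
}

#' Simulate a hypnogram from a stage-transition model
#'
#' @param model a [stage_markov_model()].
#' @param n_epochs number of 30-s epochs (>= 1).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param start_time `POSIXct` (UTC) start of the first epoch.
#' @return a five-class [hypnogram()].
#' @export
simulate_hypnogram <- function(model, n_epochs, seed = 1L,
                               start_time = utc("2024-01-01 23:00:00")) {
  stopifnot(inherits(model, "stage_markov_model"))
  if (n_epochs < 1L) stop("n_epochs must be >= 1")
  P <- model$transition_matrix
  labels <- integer(n_epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labels[1L] <- sample.int(5L, 1L, prob = model$initial_distribution)
  if (n_epochs > 1L) {
    u <- runif(n_epochs - 1L)
    cums <- apply(P, 1L, cumsum) # 5 x 5, column = from-state
    for (t in 2:n_epochs) {
      labels[t] <- findInterval(u[t - 1L], cums[, labels[t - 1L]]) + 1L
    }
  }
  hypnogram(start_time, STAGES5[labels])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Stage-dependent movement model
#'
#' Per-stage parameters of the synthetic signal generator. Stages cover the
#' five AASM classes plus `"A"`, out-of-bed ambulatory wake used for the
#' daytime portion of free-living days. Noise SDs are total per-axis white
#' noise (device noise floor included), in milli-g.
#'
#' @param stages character vector of stage labels the model covers.
#' @param noise_sd per-axis white-noise SD per stage (mg).
#' @param burst_rate movement bursts per minute per stage.
#' @param burst_amplitude_sd per-axis burst amplitude SD (mg).
#' @param burst_duration burst duration (seconds).
#' @param posture_shift_rate posture shifts per hour per stage.
#' @param orientation_drift_sd rotation angle SD per posture shift (degrees).
#' @return an object of class `movement_model` (a data.frame, one row per
#'   stage).
#' @export
movement_model <- function(stages, noise_sd, burst_rate, burst_amplitude_sd,
                           burst_duration, posture_shift_rate,
                           orientation_drift_sd) {
  df <- data.frame(
    stage = stages,
    noise_sd = noise_sd,
    burst_rate = burst_rate,
    burst_amplitude_sd = burst_amplitude_sd,
    burst_duration = burst_duration,
    posture_shift_rate = posture_shift_rate,
    orientation_drift_sd = orientation_drift_sd,
    stringsAsFactors = FALSE
  )
  num <- df[, -1]
  if (any(num < 0)) stop("all movement-model rates and SDs must be >= 0")
  rownames(df) <- df$stage
  class(df) <- c("movement_model", "data.frame")
  df
}

#' Default movement preset
#'
#' Noise floors sit just above typical wrist-device noise so that worn
#' epochs are never mistaken for stationarity, and movement energy is
#' ordered wake > REM > N1 > N2 > N3. Bursts have a fast-attack /
#' slow-decay envelope, mimicking the temporal asymmetry of real wrist
#' movements.
#'
#' @return a [movement_model()].
#' @export
default_movement_model <- function() {
  movement_model(
    stages = c("W", "N1", "N2", "N3", "R", "A"),
    noise_sd = c(33, 16, 15.3, 15, 18, 60),
    burst_rate = c(3, 0.8, 0.4, 0.1, 1.5, 10),
    burst_amplitude_sd = c(120, 40, 25, 15, 60, 250),
    burst_duration = c(2, 1.5, 1.5, 1.5, 2, 2.5),
    posture_shift_rate = c(8, 3, 1.5, 0.8, 2, 40),
    orientation_drift_sd = c(20, 15, 10, 8, 12, 45)
  )
}

# Rotate unit vector v by angle theta (radians) about a random axis.
rotate_random <- function(v, theta) {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  # Rodrigues' rotation formula
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Core signal synthesis over an arbitrary stage label sequence (30-s epochs).
# Returns an n_samples x 3 matrix in g. Uses the current RNG stream.
sim_signal <- function(labels, movement, sample_rate) {
  mm <- as.data.frame(movement)
  bad <- setdiff(unique(labels), rownames(mm))
  if (length(bad) > 0L) stop("movement model missing stage(s): ", paste(bad, collapse = ", "))
  n_ep <- length(labels)
  spe <- as.integer(round(sample_rate * EPOCH_SECONDS)) # samples per epoch
  n <- n_ep * spe

  par <- mm[labels, , drop = FALSE]

  # --- gravity: piecewise-constant orientation, changing at posture shifts
  p_shift <- pmin(1, par$posture_shift_rate / 120) # per-epoch probability
  shift <- runif(n_ep) < p_shift
  g <- rnorm(3)
  g <- g / sqrt(sum(g^2))
  grav <- matrix(0, n_ep, 3)
  for (e in seq_len(n_ep)) {
    if (shift[e]) {
      theta <- rnorm(1, 0, par$orientation_drift_sd[e] * pi / 180)
      g <- rotate_random(g, theta)
    }
    grav[e, ] <- g
  }
  sig <- grav[rep(seq_len(n_ep), each = spe), , drop = FALSE]

  # --- white noise, per-stage SD (mg -> g)
  sd_per_sample <- rep(par$noise_sd, each = spe) / 1000
  if (any(sd_per_sample > 0)) {
    sig <- sig + matrix(rnorm(3L * n, 0, rep(sd_per_sample, 3L)), n, 3L)
  }

  # --- movement bursts: fast attack, slow decay, band-limited oscillation
  n_bursts <- rpois(n_ep, par$burst_rate * (EPOCH_SECONDS / 60))
  burst_ep <- rep(seq_len(n_ep), n_bursts)
  if (length(burst_ep) > 0L) {
    for (e in burst_ep) {
      dur <- par$burst_duration[e]
      ns <- max(2L, as.integer(round(dur * sample_rate)))
      start <- (e - 1L) * spe + sample.int(spe, 1L)
      idx <- start:min(start + ns - 1L, n)
      tt <- (seq_along(idx) - 1) / sample_rate
      attack <- 0.2 * dur
      env <- ifelse(tt < attack, tt / attack, exp(-(tt - attack) / (0.3 * dur)))
      f <- runif(1, 0.8, 3)
      amp <- rnorm(3, 0, par$burst_amplitude_sd[e] / 1000)
      ph <- runif(3, 0, 2 * pi)
      # a movement burst is a damped directional transient (the arm
      # accelerates and decelerates along a path) with an oscillatory
      # component on top; the fast-attack / slow-decay envelope makes the
      # signal asymmetric in time
      for (a in 1:3) {
        sig[idx, a] <- sig[idx, a] +
          amp[a] * env * (0.7 + 0.3 * sin(2 * pi * f * tt + ph[a]))
      }
    }
  }
  colnames(sig) <- c("x", "y", "z")
  sig
}

#' Simulate a tri-axial recording for a hypnogram
#'
#' The signal is a slowly varying unit-norm gravity vector (piecewise
#' constant between posture shifts) plus stage-dependent movement bursts
#' and white noise. With all noise and burst parameters zero the signal is
#' pure gravity with Euclidean norm exactly 1 g.
#'
#' @param hyp a [hypnogram()] (or any stage label sequence via
#'   `labels`/`start_time` internally).
#' @param movement a [movement_model()].
#' @param sample_rate sampling rate in Hz (>= 30).
#' @param seed integer seed; identical seeds give bit-identical signals.
#' @return a [raw_recording()] spanning the hypnogram.
#' @export
simulate_recording <- function(hyp, movement = default_movement_model(),
                               sample_rate = 30, seed = 1L) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(hyp) < 1L) stop("hypnogram is empty")
  if (sample_rate < 30) stop("sample_rate must be >= 30 Hz")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sig <- sim_signal(as.character(hyp$stage), movement, sample_rate)
  raw_recording(sig, hyp$epoch_start[1], sample_rate)
}

#' Simulate one multi-night synthetic subject
#'
#' Assembles, for each night, a continuous wear block running from
#' `wear_start_hour` to `wear_end_hour` the next day. Epochs outside the
#' bed interval carry ambulatory-wake (`"A"`) movement; the bed interval is
#' filled by a Markov-chain hypnogram. Diary times are the true sleep
#' onset/offset with uniform(-15, +15) min self-report noise. Optional
#' non-wear gaps (constant gravity, zero noise) are injected into the
#' daytime portion and recorded as ground truth.
#'
#' @param subject_id subject identifier.
#' @param n_nights number of nights.
#' @param stage_model a [stage_markov_model()].
#' @param movement a [movement_model()].
#' @param sample_rate Hz (>= 30).
#' @param seed integer seed.
#' @param start_date first calendar date (`Date` or string).
#' @param wear_start_hour wear-block start hour-of-day (fraction allowed).
#' @param wear_end_hour wear-block end hour-of-day next day.
#' @param nonwear_minutes if > 0, one injected non-wear gap of this length
#'   per night, placed in the evening out-of-bed period.
#' @return an object of class `synthetic_subject`: list with `subject_id`,
#'   `recordings` (one [raw_recording()] per wear block), `hypnograms`
#'   (one per night), `diary` (data.frame), `nonwear_truth` (data.frame of
#'   `[start, end)` intervals).
#' @export
simulate_subject <- function(subject_id, n_nights = 2,
                             stage_model = default_stage_model(),
                             movement = default_movement_model(),
                             sample_rate = 30, seed = 1L,
                             start_date = "2024-03-04",
                             wear_start_hour = 20, wear_end_hour = 10,
                             nonwear_minutes = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  date0 <- as.Date(start_date)
  recordings <- list()
  hypnograms <- list()
  diary <- list()
  nonwear <- list()

  # subject-level habitual sleep timing and duration
  subj_bed_clock <- rnorm(1, parse_clock(stage_model$bedtime_mean),
                          stage_model$bedtime_subject_sd / 60)
  subj_tib_mean <- rnorm(1, stage_model$time_in_bed_mean,
                         stage_model$time_in_bed_subject_sd / 60)

  for (night in seq_len(n_nights)) {
    day <- date0 + (night - 1L)
    block_start <- utc(paste(day, "00:00:00")) + wear_start_hour * 3600
    block_end <- utc(paste(day + 1L, "00:00:00")) + wear_end_hour * 3600

    # bed timing: snap to the 30-s epoch grid of the block
    bed_clock <- rnorm(1, subj_bed_clock, stage_model$bedtime_sd / 60)
    bed_start <- utc(paste(day, "00:00:00")) + bed_clock * 3600
    tib_h <- rnorm(1, subj_tib_mean, stage_model$time_in_bed_sd / 60)
    tib_h <- max(tib_h, 4)
    snap <- function(t) {
      block_start + round(as.numeric(t - block_start, units = "secs") /
                            EPOCH_SECONDS) * EPOCH_SECONDS
    }
    bed_start <- snap(bed_start)
    bed_end <- snap(bed_start + tib_h * 3600)
    bed_start <- max(bed_start, block_start)
    bed_end <- min(bed_end, block_end)
    n_bed <- as.integer(as.numeric(bed_end - bed_start, units = "secs") / EPOCH_SECONDS)

    hyp_seed <- sample.int(.Machine$integer.max, 1L)
    hyp <- simulate_hypnogram(stage_model, n_bed, seed = hyp_seed,
                              start_time = bed_start)
    n_total <- as.integer(as.numeric(block_end - block_start, units = "secs") /
                            EPOCH_SECONDS)
    labels <- rep("A", n_total)
    bed_off <- as.integer(as.numeric(bed_start - block_start, units = "secs") /
                            EPOCH_SECONDS)
    labels[bed_off + seq_len(n_bed)] <- as.character(hyp$stage)

    sig <- sim_signal(labels, movement, sample_rate)
    rec <- raw_recording(sig, block_start, sample_rate, subject_id)

    # injected non-wear: constant gravity, zero noise, in the evening period
    if (nonwear_minutes > 0) {
      spe <- as.integer(round(sample_rate * EPOCH_SECONDS))
      nw_epochs <- as.integer(ceiling(nonwear_minutes * 60 / EPOCH_SECONDS))
      avail <- bed_off - nw_epochs - 2L
      if (avail > 1L) {
        nw_start_ep <- sample.int(avail, 1L)
        idx <- ((nw_start_ep - 1L) * spe + 1L):((nw_start_ep - 1L + nw_epochs) * spe)
        gvec <- rnorm(3)
        gvec <- gvec / sqrt(sum(gvec^2))
        rec$data[idx, ] <- matrix(gvec, length(idx), 3, byrow = TRUE)
        nonwear[[length(nonwear) + 1L]] <- data.frame(
          subject_id = subject_id,
          start = block_start + (nw_start_ep - 1L) * EPOCH_SECONDS,
          end = block_start + (nw_start_ep - 1L + nw_epochs) * EPOCH_SECONDS
        )
      }
    }

    # diary: truth +/- uniform(-15, 15) min
    st <- as.character(hyp$stage)
    onset_i <- match(TRUE, st != "W")
    offset_i <- if (any(st != "W")) max(which(st != "W")) else NA_integer_
    if (!is.na(onset_i)) {
      onset <- hyp$epoch_start[onset_i]
      offset <- hyp$epoch_start[offset_i] + EPOCH_SECONDS
      diary[[length(diary) + 1L]] <- data.frame(
        subject_id = subject_id,
        night_date = day,
        fell_asleep = onset + round(runif(1, -15, 15) * 60),
        woke_up = offset + round(runif(1, -15, 15) * 60)
      )
    }

    recordings[[night]] <- rec
    hypnograms[[night]] <- hyp
  }

  structure(
    list(
      subject_id = subject_id,
      n_nights = n_nights,
      recordings = recordings,
      hypnograms = hypnograms,
      diary = if (length(diary)) do.call(rbind, diary) else NULL,
      nonwear_truth = if (length(nonwear)) do.call(rbind, nonwear) else NULL
    ),
    class = "synthetic_subject"
  )
}

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects.
#' @param n_nights nights per subject.
#' @param seed master integer seed; per-subject seeds are derived from it.
#' @param sample_rate Hz.
#' @param wear_start_hour,wear_end_hour daily wear block (see
#'   [simulate_subject()]).
#' @param nonwear_minutes injected non-wear gap length per night (0 = none).
#' @param stage_model,movement generator presets.
#' @param start_date first calendar date.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 4, n_nights = 2, seed = 1L,
                          sample_rate = 30, wear_start_hour = 20,
                          wear_end_hour = 10, nonwear_minutes = 0,
                          stage_model = default_stage_model(),
                          movement = default_movement_model(),
                          start_date = "2024-03-04") {
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a cohort and write it to disk
#'
#' Writes, per subject, one recording CSV per wear block and one hypnogram
#' CSV per night, plus a cohort-level diary CSV and a plain-text key-value
#' manifest listing seeds and files. Re-running with the same config
#' reproduces byte-identical CSV content.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.txt`).
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  manifest <- list()
  diaries <- list()
  nonwear <- list()
  subject_seeds <- config$seed + seq_len(config$n_subjects) * 1000L

  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", i)
    subj <- simulate_subject(
      sid, config$n_nights,
      stage_model = config$stage_model, movement = config$movement,
      sample_rate = config$sample_rate, seed = subject_seeds[i],
      start_date = config$start_date,
      wear_start_hour = config$wear_start_hour,
      wear_end_hour = config$wear_end_hour,
      nonwear_minutes = config$nonwear_minutes
    )
    for (night in seq_len(config$n_nights)) {
      rec_file <- file.path(out_dir, sprintf("%s_night%02d_acc.csv", sid, night))
      write_recording_csv(subj$recordings[[night]], rec_file)
      hyp <- subj$hypnograms[[night]]
      hyp_file <- file.path(out_dir, sprintf("%s_night%02d_hypnogram.csv", sid, night))
      data.table::fwrite(
        data.table::data.table(epoch_start = hyp$epoch_start,
                               stage = as.character(hyp$stage)),
        hyp_file, dateTimeAs = "ISO"
      )
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = sid, night = night, seed = subject_seeds[i],
        recording = basename(rec_file), hypnogram = basename(hyp_file)
      )
    }
    if (!is.null(subj$diary)) diaries[[length(diaries) + 1L]] <- subj$diary
    if (!is.null(subj$nonwear_truth)) {
      nonwear[[length(nonwear) + 1L]] <- subj$nonwear_truth
    }
  }

  if (length(diaries)) {
    data.table::fwrite(data.table::as.data.table(do.call(rbind, diaries)),
                       file.path(out_dir, "diary.csv"), dateTimeAs = "ISO")
  }
  if (length(nonwear)) {
    data.table::fwrite(data.table::as.data.table(do.call(rbind, nonwear)),
                       file.path(out_dir, "nonwear_truth.csv"), dateTimeAs = "ISO")
  }
  mdf <- if (length(manifest)) do.call(rbind, manifest) else {
    data.frame(subject_id = character(), night = integer(), seed = integer(),
               recording = character(), hypnogram = character())
  }
  con <- file(file.path(out_dir, "manifest.txt"), "w")
  writeLines(c(
    sprintf("n_subjects: %d", config$n_subjects),
    sprintf("n_nights: %d", config$n_nights),
    sprintf("master_seed: %d", config$seed),
    sprintf("sample_rate: %g", config$sample_rate)
  ), con)
  if (nrow(mdf) > 0L) {
    writeLines(sprintf("file: %s subject: %s seed: %d",
                       mdf$recording, mdf$subject_id, mdf$seed), con)
  }
  close(con)
  invisible(mdf)
}
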