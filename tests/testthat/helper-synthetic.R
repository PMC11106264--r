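# Shared fixture builders and independent oracles. Fixtures are generated
# in code at test time; oracles are deliberately naive re-implementations
# kept separate from the package's own code paths.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# one labelled night: epoch tensor + ground-truth hypnogram
make_night <- function(sid, k, n_epochs = 120, start = "2024-01-01 23:00:00") {
  hyp <- simulate_hypnogram(default_stage_model(), n_epochs,
                            seed = 1000L + 17L * k, start_time = utc(start))
  rec <- simulate_recording(hyp, default_movement_model(), 30,
                            seed = 1001L + 17L * k)
  list(epochs = epochize(rec), hypnogram = hyp, subject_id = sid)
}

make_cohort_nights <- function(n_subjects, n_nights, n_epochs = 120) {
  nights <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (n in seq_len(n_nights)) {
      k <- k + 1L
      start <- format(as.Date("2024-01-01") + (n - 1L))
      nights[[k]] <- make_night(sprintf("S%02d", s), k, n_epochs,
                                start = paste(start, "23:00:00"))
    }
  }
  nights
}

# burst-dense, temporally asymmetric windows (fast-attack / slow-decay
# movement transients) for self-supervision tests
make_burst_tensors <- function(n_subjects, n_epochs = 200) {
  mm <- default_movement_model()
  mm["W", "burst_rate"] <- 12
  lapply(seq_len(n_subjects), function(k) {
    hyp <- hypnogram(utc("2024-01-01 23:00:00"), rep("W", n_epochs))
    epochize(simulate_recording(hyp, mm, 30, seed = 501L + 11L * k))
  })
}

# --- independent oracles -----------------------------------------------

# agreement metrics by direct formula evaluation on a count matrix
oracle_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  K <- nrow(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- (p_o - p_e) / (1 - p_e)
  sens <- spec <- prec <- f1 <- numeric(K)
  for (i in seq_len(K)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else NA
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else NA
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else NA
    f1[i] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA
  }
  list(kappa = kappa, macro_f1 = mean(f1, na.rm = TRUE),
       balanced_accuracy = mean(sens, na.rm = TRUE), accuracy = p_o,
       sens = sens, spec = spec, prec = prec)
}

# Viterbi by exhaustive enumeration of all K^T state paths
oracle_viterbi <- function(log_init, log_trans, log_emit) {
  K <- length(log_init)
  Tn <- nrow(log_emit)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- as.integer(paths[r, ])
    lp <- log_init[p[1]] + log_emit[1, p[1]]
    if (Tn > 1) {
      for (t in 2:Tn) lp <- lp + log_trans[p[t - 1], p[t]] + log_emit[t, p[t]]
    }
    if (lp > best + 1e-12) {
      best <- lp
      best_path <- p
    }
  }
  best_path
}

# ICC(2,1) via explicit two-way ANOVA sums of squares (long-format loop)
oracle_icc21 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ssr <- ssc <- sse <- 0
  for (i in seq_len(n)) {
    ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  }
  for (j in seq_len(k)) {
    ssc <- ssc + n * (mean(m[, j]) - grand)^2
  }
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
    }
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# per-night sleep parameters by naive epoch counting
oracle_night_summary <- function(stages, tib_hours) {
  n <- length(stages)
  asleep <- stages != "W"
  tst <- sum(asleep) * 30 / 3600
  onset <- match(TRUE, asleep)
  waso <- if (is.na(onset)) 0 else sum(stages[onset:n] == "W") * 30 / 60
  rem <- sum(stages == "R") * 30 / 3600
  nrem <- sum(stages %in% c("N1", "N2", "N3")) * 30 / 3600
  list(
    tst = tst, eff = 100 * tst / tib_hours, waso = waso, rem = rem,
    nrem = nrem,
    rem_ratio = if (tst > 0) 100 * rem / tst else NA_real_,
    nrem_ratio = if (tst > 0) 100 * nrem / tst else NA_real_
  )
}
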