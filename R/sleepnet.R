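# SleepNet: deep sleep stager. A 1D-convolutional pre-activation residual
# network extracts a feature vector from each 30-s window; a bidirectional
# LSTM integrates the night's epoch sequence; two fully-connected layers
# predict the five AASM stages. The same extractor is pre-trainable by
# multi-task self-supervision (transformation discrimination) on unlabeled
# windows. All compute lives in compiled code; this file owns configs,
# initialisation, batching, Adam and the cross-validation protocol.

#' SleepNet configuration
#'
#' @param preset `"tiny"` (test-scale, < 100k parameters) or `"resnet17"`
#'   (17 convolutional layers with doubling channel widths).
#' @param n_classes number of output stages (5 at training time).
#' @param input_len samples per window (900 = 30 s x 30 Hz).
#' @param lstm_hidden LSTM hidden size per direction.
#' @param fc_hidden width of the first fully-connected layer.
#' @param sequence_length epochs per training sequence (random crops);
#'   inference always runs on the full night.
#' @param dropout dropout probability on the LSTM output during training.
#' @param learning_rate,batch_size,max_epochs,early_stop_patience Adam
#'   training schedule (batch_size counts sequences).
#' @param class_weighting inverse-frequency class weights in the loss.
#' @param center_input subtract each window's per-axis mean before the stem
#'   convolution (fixed input-normalisation layer); keeps the slowly
#'   varying gravity component from dominating the movement signal.
#' @param ssl_head input of the self-supervision heads: `"map"` (final
#'   feature map before pooling, time-order preserving) or `"gap"`
#'   (pooled feature vector).
#' @param input_vm append the Euclidean vector magnitude as a fourth input
#'   channel (fixed rectifying feature; gives the convolutions direct
#'   access to the movement envelope).
#' @param seed integer seed fixing initialisation and batching.
#' @param stem,blocks optional explicit conv specs overriding the preset:
#'   `stem = list(in, out, k, stride)`, `blocks` a list of the same for
#'   each residual block's first conv (second conv is `out -> out`,
#'   stride 1; a 1x1 projection shortcut is added when shape changes).
#' @return a list of class `sleepnet_config`.
#' @export
sleepnet_config <- function(preset = c("tiny", "resnet17"), n_classes = 5L,
                            input_len = 900L, lstm_hidden = NULL,
                            fc_hidden = NULL, sequence_length = 64L,
                            dropout = 0, learning_rate = 0.005,
                            batch_size = 8L, max_epochs = 12L,
                            early_stop_patience = 3L, class_weighting = TRUE,
                            center_input = TRUE, ssl_head = c("map", "gap"),
                            input_vm = TRUE, seed = 1L, stem = NULL,
                            blocks = NULL) {
  ssl_head <- match.arg(ssl_head)
  preset <- match.arg(preset)
  n_in <- if (input_vm) 4L else 3L
  if (is.null(stem) || is.null(blocks)) {
    if (preset == "tiny") {
      stem <- list(`in` = n_in, out = 8L, k = 7L, stride = 4L)
      blocks <- list(
        list(`in` = 8L, out = 16L, k = 5L, stride = 4L),
        list(`in` = 16L, out = 32L, k = 5L, stride = 4L)
      )
      if (is.null(lstm_hidden)) lstm_hidden <- 24L
      if (is.null(fc_hidden)) fc_hidden <- 32L
    } else {
      stem <- list(`in` = n_in, out = 64L, k = 7L, stride = 2L)
      ch <- c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L)
      blocks <- vector("list", 8L)
      prev <- 64L
      for (i in 1:8) {
        blocks[[i]] <- list(`in` = prev, out = ch[i], k = 5L,
                            stride = if (i %% 2L == 1L) 2L else 1L)
        prev <- ch[i]
      }
      if (is.null(lstm_hidden)) lstm_hidden <- 128L
      if (is.null(fc_hidden)) fc_hidden <- 128L
    }
  }
  if (is.null(lstm_hidden)) lstm_hidden <- 24L
  if (is.null(fc_hidden)) fc_hidden <- 32L
  structure(
    list(preset = preset, n_classes = as.integer(n_classes),
         input_len = as.integer(input_len), stem = stem, blocks = blocks,
         lstm_hidden = as.integer(lstm_hidden),
         fc_hidden = as.integer(fc_hidden),
         sequence_length = as.integer(sequence_length), dropout = dropout,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         class_weighting = class_weighting, center_input = center_input,
         ssl_head = ssl_head, input_vm = input_vm, seed = as.integer(seed)),
    class = "sleepnet_config"
  )
}

extractor_feature_dim <- function(cfg) {
  cfg$blocks[[length(cfg$blocks)]]$out
}

# temporal length of the extractor's final feature map for a given input
# length (stem + each block's strided conv, "same" padding)
extractor_output_len <- function(cfg, input_len = cfg$input_len) {
  out_len <- function(T, k, stride) {
    pad <- (k - 1L) %/% 2L
    (T + 2L * pad - k) %/% stride + 1L
  }
  T <- out_len(input_len, cfg$stem$k, cfg$stem$stride)
  for (b in cfg$blocks) T <- out_len(T, b$k, b$stride)
  T
}

# He-normal conv/FC init, uniform LSTM init, forget-gate bias 1.
sleepnet_init_params <- function(cfg, seed = cfg$seed, with_ssl_heads = FALSE,
                                 n_ssl_tasks = 3L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- list()
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  s <- cfg$stem
  p$stem_W <- he(s$out, s$`in` * s$k)
  p$stem_b <- numeric(s$out)
  for (i in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[i]]
    pre <- sprintf("b%d_", i)
    p[[paste0(pre, "bn1_g")]] <- rep(1, b$`in`)
    p[[paste0(pre, "bn1_b")]] <- numeric(b$`in`)
    p[[paste0(pre, "W1")]] <- he(b$out, b$`in` * b$k)
    p[[paste0(pre, "b1")]] <- numeric(b$out)
    p[[paste0(pre, "bn2_g")]] <- rep(1, b$out)
    p[[paste0(pre, "bn2_b")]] <- numeric(b$out)
    p[[paste0(pre, "W2")]] <- he(b$out, b$out * b$k)
    p[[paste0(pre, "b2")]] <- numeric(b$out)
    if (b$`in` != b$out || b$stride != 1L) {
      p[[paste0(pre, "Ws")]] <- he(b$out, b$`in`)
      p[[paste0(pre, "bs")]] <- numeric(b$out)
    }
  }
  Fdim <- extractor_feature_dim(cfg)
  p$final_bn_g <- rep(1, Fdim)
  p$final_bn_b <- numeric(Fdim)
  H <- cfg$lstm_hidden
  lu <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)
  for (d in c("fwd", "bwd")) {
    p[[sprintf("lstm_%s_W", d)]] <- lu(4L * H, Fdim)
    p[[sprintf("lstm_%s_U", d)]] <- lu(4L * H, H)
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1 # forget-gate bias
    p[[sprintf("lstm_%s_b", d)]] <- b
  }
  p$fc1_W <- he(cfg$fc_hidden, 2L * H)
  p$fc1_b <- numeric(cfg$fc_hidden)
  p$fc2_W <- he(cfg$n_classes, cfg$fc_hidden)
  p$fc2_b <- numeric(cfg$n_classes)
  if (with_ssl_heads) {
    # "map" heads read the final feature map before pooling (F x T_final)
    hdim <- if (identical(cfg$ssl_head, "gap")) Fdim
            else Fdim * extractor_output_len(cfg)
    p$ssl_W <- he(n_ssl_tasks, hdim)
    p$ssl_b <- numeric(n_ssl_tasks)
  }
  p
}

sleepnet_init_run_stats <- function(cfg) {
  rs <- list()
  for (i in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[i]]
    rs[[sprintf("b%d_bn1_mean", i)]] <- numeric(b$`in`)
    rs[[sprintf("b%d_bn1_var", i)]] <- rep(1, b$`in`)
    rs[[sprintf("b%d_bn2_mean", i)]] <- numeric(b$out)
    rs[[sprintf("b%d_bn2_var", i)]] <- rep(1, b$out)
  }
  Fdim <- extractor_feature_dim(cfg)
  rs$final_bn_mean <- numeric(Fdim)
  rs$final_bn_var <- rep(1, Fdim)
  rs
}

#' Build a SleepNet model handle
#'
#' Instantiates parameters (seeded) and batch-norm running statistics for
#' a configuration. Two builds with the same config seed have identical
#' initial parameters.
#'
#' @param cfg a [sleepnet_config()].
#' @param with_ssl_heads also create the self-supervision heads.
#' @param n_ssl_tasks number of self-supervision tasks.
#' @return an object of class `sleepnet_model`.
#' @export
build_sleepnet <- function(cfg, with_ssl_heads = FALSE, n_ssl_tasks = 3L) {
  stopifnot(inherits(cfg, "sleepnet_config"))
  n_in <- if (isTRUE(cfg$input_vm)) 4L else 3L
  if (cfg$stem$`in` != n_in) {
    stop("stem input channels must match the input layer (", n_in, ")")
  }
  structure(
    list(cfg = cfg,
         params = sleepnet_init_params(cfg, cfg$seed, with_ssl_heads,
                                       n_ssl_tasks),
         run_stats = sleepnet_init_run_stats(cfg),
         trained = FALSE),
    class = "sleepnet_model"
  )
}

#' Number of trainable parameters
#' @param model a `sleepnet_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.sleepnet_model <- function(x, ...) {
  cat(sprintf(
    "<sleepnet_model> preset=%s, %d conv blocks, lstm=%d, %d parameters%s\n",
    x$cfg$preset, length(x$cfg$blocks), x$cfg$lstm_hidden, count_params(x),
    if (x$trained) " (trained)" else ""
  ))
  invisible(x)
}

# Forward pass over a cube of windows organised as B sequences x S epochs.
# Returns probabilities (n_classes x B*S).
sleepnet_forward <- function(model, X, B, S, training = FALSE) {
  out <- cpp_sleepnet_pass(
    X, rep(-1L, B * S), model$params, model$cfg, model$run_stats,
    rep(1, model$cfg$n_classes), as.integer(B), as.integer(S),
    training, FALSE, model$cfg$dropout
  )
  out$probs
}

# ---------------------------------------------------------------------------
# Adam on a named list of parameter arrays

adam_state <- function(params) {
  list(m = lapply(params, function(p) numeric(length(p))),
       v = lapply(params, function(p) numeric(length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (n in names(grads)) {
    g <- as.numeric(grads[[n]])
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * g
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * g^2
    mhat <- state$m[[n]] / (1 - beta1^state$t)
    vhat <- state$v[[n]] / (1 - beta2^state$t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && grepl("_(W|Ws|W1|W2|U)$", n)) {
      step <- step + lr * weight_decay * as.numeric(params[[n]])
    }
    params[[n]] <- params[[n]] - step
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# self-supervision

#' Self-supervision task configuration
#'
#' @param tasks subset of `"time_reversal"`, `"segment_permutation"`,
#'   `"time_warp"`.
#' @param p_apply per-task application probability.
#' @param permutation_segments segments for the permutation task.
#' @param warp_knots,warp_sigma knot count and log-scale SD of the random
#'   monotone time warp.
#' @param jitter_sd SD (in g) of fresh white noise added to every drawn
#'   window. Jitter is an augmentation, not a task: it stops the
#'   discriminator from keying on the idiosyncratic noise pattern of
#'   individual windows instead of properties of the transformations.
#' @return list of class `ssl_task_config`.
#' @export
ssl_task_config <- function(tasks = c("time_reversal", "segment_permutation",
                                      "time_warp"),
                            p_apply = 0.5, permutation_segments = 4L,
                            warp_knots = 4L, warp_sigma = 0.3,
                            jitter_sd = 0.02) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (length(tasks) < 1L) stop("at least one self-supervision task required")
  if (p_apply < 0 || p_apply > 1) stop("p_apply must be in [0, 1]")
  structure(list(tasks = tasks, p_apply = p_apply,
                 permutation_segments = as.integer(permutation_segments),
                 warp_knots = as.integer(warp_knots), warp_sigma = warp_sigma,
                 jitter_sd = jitter_sd),
            class = "ssl_task_config")
}

# individual transforms (3 x L matrices in, same shape out)
transform_time_reversal <- function(w) w[, ncol(w):1, drop = FALSE]

transform_segment_permutation <- function(w, n_segments, perm = NULL) {
  L <- ncol(w)
  bounds <- round(seq(0, L, length.out = n_segments + 1))
  segs <- lapply(seq_len(n_segments),
                 function(i) w[, (bounds[i] + 1):bounds[i + 1], drop = FALSE])
  if (is.null(perm)) {
    repeat {
      perm <- sample.int(n_segments)
      if (any(perm != seq_len(n_segments))) break
    }
  }
  do.call(cbind, segs[perm])
}

transform_time_warp <- function(w, knots, sigma) {
  L <- ncol(w)
  # monotone piecewise-linear time map with random segment speeds
  speeds <- exp(rnorm(knots, 0, sigma))
  knot_x <- seq(0, 1, length.out = knots + 1)
  knot_y <- c(0, cumsum(speeds)) / sum(speeds)
  t_orig <- seq(0, 1, length.out = L)
  t_warp <- approx(knot_x, knot_y, xout = t_orig)$y
  out <- w
  for (a in seq_len(nrow(w))) {
    out[a, ] <- approx(t_orig, w[a, ], xout = t_warp, rule = 2)$y
  }
  out
}

#' Apply self-supervision transformations to one window
#'
#' Each enabled task is applied independently with probability `p_apply`;
#' the returned labels record which were applied. Output shape always
#' equals the input shape (the time warp resamples back to the original
#' length).
#'
#' @param window 3 x L numeric matrix.
#' @param task_cfg an [ssl_task_config()].
#' @return list with `window` (transformed) and `labels` (named 0/1
#'   vector, one entry per enabled task). Uses the current RNG stream.
#' @export
apply_ssl_transform <- function(window, task_cfg = ssl_task_config()) {
  stopifnot(is.matrix(window), nrow(window) == 3L)
  labels <- setNames(numeric(length(task_cfg$tasks)), task_cfg$tasks)
  w <- window
  for (task in task_cfg$tasks) {
    if (runif(1) < task_cfg$p_apply) {
      labels[task] <- 1
      w <- switch(task,
        time_reversal = transform_time_reversal(w),
        segment_permutation =
          transform_segment_permutation(w, task_cfg$permutation_segments),
        time_warp = transform_time_warp(w, task_cfg$warp_knots,
                                        task_cfg$warp_sigma)
      )
    }
  }
  list(window = w, labels = labels)
}

# rank-based AUC of scores against binary labels
auc_rank <- function(scores, labels) {
  pos <- scores[labels > 0.5]
  neg <- scores[labels <= 0.5]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Pretrain the feature extractor by multi-task self-supervision
#'
#' Unlabeled windows are transformed by the enabled tasks; the extractor is
#' trained jointly with one binary head per task to discriminate which
#' transformations were applied (summed binary cross-entropies). Held-out
#' subjects provide a per-task AUC.
#'
#' @param model a [build_sleepnet()] model (heads are added if absent).
#' @param unlabeled list of `epoch_tensor` objects (>= 2 subjects).
#' @param ssl_cfg an [ssl_task_config()].
#' @param epochs,batch_size,learning_rate training schedule (windows per
#'   batch).
#' @param holdout_frac fraction of subjects held out for task AUC.
#' @param seed integer seed.
#' @return list with `model` (extractor weights updated), `auc` (named
#'   per-task held-out AUC), `loss_initial`, `loss_final`.
#' @export
pretrain_ssl <- function(model, unlabeled, ssl_cfg = ssl_task_config(),
                         epochs = 6L, batch_size = 64L, learning_rate = 0.003,
                         weight_decay = 1e-3, holdout_frac = 0.25, seed = 1L) {
  stopifnot(inherits(model, "sleepnet_model"))
  if (length(unlabeled) < 2L) stop("need unlabeled epochs from >= 2 subjects")
  n_tasks <- length(ssl_cfg$tasks)
  if (!is.null(model$params$ssl_W) &&
      nrow(model$params$ssl_W) != n_tasks) {
    model$params$ssl_W <- NULL
    model$params$ssl_b <- NULL
  }
  if (is.null(model$params$ssl_W)) {
    heads <- sleepnet_init_params(model$cfg, model$cfg$seed,
                                  with_ssl_heads = TRUE,
                                  n_ssl_tasks = n_tasks)
    model$params$ssl_W <- heads$ssl_W
    model$params$ssl_b <- heads$ssl_b
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_hold <- max(1L, floor(length(unlabeled) * holdout_frac))
  hold_idx <- seq(length(unlabeled) - n_hold + 1L, length(unlabeled))

  base_windows <- function(tensors) {
    wins <- list()
    for (tensor in tensors) {
      arr <- tensor$epochs
      for (e in which(tensor$wear_mask)) {
        wins[[length(wins) + 1L]] <- matrix(arr[e, , ], nrow = 3L)
      }
    }
    wins
  }
  # transformations are re-drawn on every visit, so the discriminator can
  # only succeed through properties of the transformation itself
  draw_set <- function(wins, idx = seq_along(wins)) {
    X <- array(0, dim = c(3L, ncol(wins[[1]]), length(idx)))
    y <- matrix(0, length(ssl_cfg$tasks), length(idx))
    for (i in seq_along(idx)) {
      tr <- apply_ssl_transform(wins[[idx[i]]], ssl_cfg)
      w <- tr$window
      if (ssl_cfg$jitter_sd > 0) {
        w <- w + matrix(rnorm(length(w), 0, ssl_cfg$jitter_sd), nrow(w))
      }
      X[, , i] <- w
      y[, i] <- tr$labels
    }
    list(X = X, y = y)
  }
  train_wins <- base_windows(unlabeled[-hold_idx])
  hold_set <- draw_set(base_windows(unlabeled[hold_idx]))

  n_train <- length(train_wins)
  st <- adam_state(model$params)
  init_set <- draw_set(train_wins)
  loss_initial <- cpp_ssl_pass(init_set$X, init_set$y, model$params,
                               model$cfg, model$run_stats, FALSE, FALSE)$loss
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_train)
    for (b0 in seq(1L, n_train, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n_train)]
      batch <- draw_set(train_wins, idx)
      out <- cpp_ssl_pass(batch$X, batch$y, model$params, model$cfg,
                          model$run_stats, TRUE, TRUE)
      model$run_stats <- out$run_stats
      upd <- adam_step(model$params, out$grads, st, learning_rate,
                       weight_decay = weight_decay)
      model$params <- upd$params
      st <- upd$state
    }
  }
  # refresh batch-norm running statistics with the final weights
  for (b0 in seq(1L, n_train, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n_train)
    batch <- draw_set(train_wins, idx)
    out <- cpp_ssl_pass(batch$X, batch$y, model$params, model$cfg,
                        model$run_stats, TRUE, FALSE)
    model$run_stats <- out$run_stats
  }
  fin_set <- draw_set(train_wins)
  fin <- cpp_ssl_pass(fin_set$X, fin_set$y, model$params, model$cfg,
                      model$run_stats, FALSE, FALSE)
  hold <- cpp_ssl_pass(hold_set$X, hold_set$y, model$params, model$cfg,
                       model$run_stats, FALSE, FALSE)
  auc <- vapply(seq_len(n_tasks), function(k) {
    auc_rank(hold$probs[k, ], hold_set$y[k, ])
  }, numeric(1))
  names(auc) <- ssl_cfg$tasks
  model$pretrained <- TRUE
  list(model = model, auc = auc, loss_initial = loss_initial,
       loss_final = fin$loss)
}

# ---------------------------------------------------------------------------
# supervised training

# Align an epoch tensor with a hypnogram; returns X cube (3 x L x n) and
# integer labels 0..4 for the matched, worn epochs.
night_training_data <- function(epochs, hyp) {
  idx <- match(as.numeric(hyp$epoch_start),
               as.numeric(epochs$epoch_start_times))
  keep <- !is.na(idx)
  keep[keep] <- epochs$wear_mask[idx[keep]]
  idx <- idx[keep]
  if (length(idx) == 0L) return(NULL)
  X <- aperm(epochs$epochs[idx, , , drop = FALSE], c(2, 3, 1))
  y <- as.integer(hyp$stage[keep]) - 1L
  list(X = X, y = y, epoch_start = hyp$epoch_start[keep])
}

sleepnet_class_weights <- function(y_all, n_classes, enabled = TRUE,
                                   cap = 10) {
  if (!enabled) return(rep(1, n_classes))
  counts <- tabulate(y_all + 1L, nbins = n_classes)
  w <- ifelse(counts > 0, sum(counts) / (n_classes * counts), 1)
  pmin(w, cap)
}

# Train on a set of nights with an optional validation set; early stopping
# on validation loss. nights: list of list(X, y).
sleepnet_fit <- function(model, train_nights, val_nights = NULL,
                         verbose = FALSE) {
  cfg <- model$cfg
  S <- cfg$sequence_length
  y_all <- unlist(lapply(train_nights, `[[`, "y"))
  cw <- sleepnet_class_weights(y_all, cfg$n_classes, cfg$class_weighting)
  st <- adam_state(model$params)
  best <- list(loss = Inf, params = model$params, run_stats = model$run_stats)
  patience_left <- cfg$early_stop_patience

  val_loss <- function(m) {
    if (is.null(val_nights) || length(val_nights) == 0L) return(NA_real_)
    tot <- 0
    n <- 0
    for (nt in val_nights) {
      len <- length(nt$y)
      out <- cpp_sleepnet_pass(nt$X, nt$y, m$params, cfg, m$run_stats, cw,
                               1L, len, FALSE, FALSE, 0)
      tot <- tot + out$loss * len
      n <- n + len
    }
    tot / n
  }

  last_train_loss <- NA_real_
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample(seq_along(train_nights))
    batch_losses <- c()
    b <- 1L
    while (b <= length(ord)) {
      take <- c()
      while (b <= length(ord) && length(take) < cfg$batch_size) {
        if (length(train_nights[[ord[b]]]$y) >= S) take <- c(take, ord[b])
        b <- b + 1L
      }
      crops <- list()
      for (ni in take) {
        nt <- train_nights[[ni]]
        len <- length(nt$y)
        off <- if (len > S) sample.int(len - S + 1L, 1L) else 1L
        sel <- off:(off + S - 1L)
        crops[[length(crops) + 1L]] <-
          list(X = nt$X[, , sel, drop = FALSE], y = nt$y[sel])
      }
      if (length(crops) == 0L) next
      B <- length(crops)
      X <- array(0, dim = c(3L, dim(crops[[1]]$X)[2], B * S))
      y <- integer(B * S)
      for (i in seq_len(B)) {
        X[, , ((i - 1L) * S + 1L):(i * S)] <- crops[[i]]$X
        y[((i - 1L) * S + 1L):(i * S)] <- crops[[i]]$y
      }
      out <- cpp_sleepnet_pass(X, y, model$params, cfg, model$run_stats, cw,
                               B, S, TRUE, TRUE, cfg$dropout)
      model$run_stats <- out$run_stats
      upd <- adam_step(model$params, out$grads, st, cfg$learning_rate)
      model$params <- upd$params
      st <- upd$state
      batch_losses <- c(batch_losses, out$loss)
    }
    # short nights (< S epochs) are trained individually
    for (nt in train_nights) {
      len <- length(nt$y)
      if (len >= S || len < 4L) next
      out <- cpp_sleepnet_pass(nt$X, nt$y, model$params, cfg, model$run_stats,
                               cw, 1L, len, TRUE, TRUE, cfg$dropout)
      model$run_stats <- out$run_stats
      upd <- adam_step(model$params, out$grads, st, cfg$learning_rate)
      model$params <- upd$params
      st <- upd$state
      batch_losses <- c(batch_losses, out$loss)
    }
    last_train_loss <- mean(batch_losses)
    vl <- val_loss(model)
    if (verbose) {
      message(sprintf("epoch %d train %.4f val %.4f", ep, last_train_loss,
                      vl))
    }
    crit <- if (is.na(vl)) last_train_loss else vl
    if (crit < best$loss - 1e-5) {
      best <- list(loss = crit, params = model$params,
                   run_stats = model$run_stats)
      patience_left <- cfg$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  model$params <- best$params
  model$run_stats <- best$run_stats
  model <- bn_recalibrate(model, train_nights)
  model$trained <- TRUE
  model$final_train_loss <- last_train_loss
  model
}

# Refresh batch-norm running statistics with frozen weights: the running
# averages lag the final parameters after optimisation, so a few
# training-mode forward sweeps over the training nights re-estimate them.
bn_recalibrate <- function(model, nights_data, sweeps = 3L) {
  cfg <- model$cfg
  for (s in seq_len(sweeps)) {
    for (nt in nights_data) {
      len <- length(nt$y)
      if (len < 2L) next
      out <- cpp_sleepnet_pass(nt$X, rep(-1L, len), model$params, cfg,
                               model$run_stats, rep(1, cfg$n_classes),
                               1L, len, TRUE, FALSE, 0)
      model$run_stats <- out$run_stats
    }
  }
  model
}

#' Train SleepNet with subject-wise cross-validation
#'
#' Five-class cross-entropy training on epoch sequences with subject-wise
#' folds; out-of-fold predictions are returned for every labelled epoch.
#' Optionally warm-starts the feature extractor from self-supervised
#' weights.
#'
#' @param model a [build_sleepnet()] model (the untrained template).
#' @param nights list of nights: each `list(epochs = <epoch_tensor>,
#'   hypnogram = <hypnogram>, subject_id = <chr>)`.
#' @param folds data.frame from [make_folds()] (subject-wise partition), or
#'   an integer k to create one from the nights' subjects.
#' @param pretrained_weights optional named parameter list (extractor
#'   weights from [pretrain_ssl()]) used as warm start.
#' @param val_frac fraction of training subjects held out for early
#'   stopping within each fold.
#' @param verbose print per-epoch losses.
#' @return list with `predictions` (data.frame: subject_id, epoch_start,
#'   p_W..p_R, label, truth, fold), `fold_models` (list of trained
#'   `sleepnet_model`s), `folds`.
#' @export
train_sleepnet <- function(model, nights, folds = 5L,
                           pretrained_weights = NULL, val_frac = 0.15,
                           verbose = FALSE) {
  stopifnot(inherits(model, "sleepnet_model"))
  subjects <- vapply(nights, `[[`, character(1), "subject_id")
  if (is.numeric(folds) && length(folds) == 1L) {
    folds <- make_folds(unique(subjects), k = folds, seed = model$cfg$seed)
  }
  if (anyDuplicated(folds$subject_id)) {
    stop("fold leakage: a subject appears in more than one fold")
  }
  missing <- setdiff(unique(subjects), folds$subject_id)
  if (length(missing) > 0L) stop("subjects missing from fold assignment: ",
                                 paste(missing, collapse = ", "))
  fold_of <- folds$fold[match(subjects, folds$subject_id)]

  data <- lapply(nights, function(nt) {
    d <- night_training_data(nt$epochs, nt$hypnogram)
    if (is.null(d)) return(NULL)
    d$subject_id <- nt$subject_id
    d
  })
  ok <- !vapply(data, is.null, logical(1))
  data <- data[ok]
  fold_of <- fold_of[ok]
  subjects <- subjects[ok]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(model$cfg$seed)

  preds <- list()
  fold_models <- list()
  for (f in sort(unique(fold_of))) {
    tr_idx <- which(fold_of != f)
    te_idx <- which(fold_of == f)
    tr_subj <- unique(subjects[tr_idx])
    n_val <- max(1L, floor(length(tr_subj) * val_frac))
    val_subj <- tr_subj[seq_len(n_val)]
    val_idx <- tr_idx[subjects[tr_idx] %in% val_subj]
    fit_idx <- setdiff(tr_idx, val_idx)

    m <- model
    m$params <- sleepnet_init_params(m$cfg, m$cfg$seed + f)
    if (!is.null(pretrained_weights)) {
      shared <- intersect(names(pretrained_weights), names(m$params))
      shared <- shared[!grepl("^(ssl_|fc|lstm)", shared)]
      m$params[shared] <- pretrained_weights[shared]
    }
    m$run_stats <- sleepnet_init_run_stats(m$cfg)
    m <- sleepnet_fit(m, data[fit_idx], data[val_idx], verbose = verbose)
    fold_models[[as.character(f)]] <- m

    for (i in te_idx) {
      nt <- data[[i]]
      len <- length(nt$y)
      probs <- sleepnet_forward(m, nt$X, 1L, len, training = FALSE)
      preds[[length(preds) + 1L]] <- data.frame(
        subject_id = nt$subject_id,
        epoch_start = nt$epoch_start,
        p_W = probs[1, ], p_N1 = probs[2, ], p_N2 = probs[3, ],
        p_N3 = probs[4, ], p_R = probs[5, ],
        label = STAGES5[max.col(t(probs))],
        truth = STAGES5[nt$y + 1L],
        fold = f
      )
    }
  }
  list(predictions = do.call(rbind, preds), fold_models = fold_models,
       folds = folds)
}

#' Predict sleep stages within a time-in-bed window
#'
#' Runs the trained stager on the epochs of a tensor inside the window;
#' inference is deterministic (batch-norm running statistics, no dropout)
#' and uses the full window as one sequence.
#'
#' @param model a trained `sleepnet_model`.
#' @param epochs an `epoch_tensor`.
#' @param window list/row with `start`, `end`; must intersect the tensor.
#' @return data.frame of class `stage_prediction` with `epoch_start`,
#'   `p_W`..`p_R` (each row sums to 1) and `label`.
#' @export
predict_stages <- function(model, epochs, window) {
  stopifnot(inherits(model, "sleepnet_model"), inherits(epochs, "epoch_tensor"))
  sel <- which(epochs$epoch_start_times >= window$start &
                 epochs$epoch_start_times < window$end &
                 epochs$wear_mask)
  if (length(sel) == 0L) stop("window contains no wear epochs of the tensor")
  X <- aperm(epochs$epochs[sel, , , drop = FALSE], c(2, 3, 1))
  probs <- sleepnet_forward(model, X, 1L, length(sel), training = FALSE)
  out <- data.frame(
    epoch_start = epochs$epoch_start_times[sel],
    p_W = probs[1, ], p_N1 = probs[2, ], p_N2 = probs[3, ],
    p_N3 = probs[4, ], p_R = probs[5, ],
    label = STAGES5[max.col(t(probs))]
  )
  class(out) <- c("stage_prediction", "data.frame")
  out
}
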