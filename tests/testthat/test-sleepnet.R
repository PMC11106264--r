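# SleepNet mechanics: configs, shape contracts, parameter counts,
# gradient correctness, transformation tasks, prediction contracts.

tiny_check_cfg <- function(seed = 42) {
  sleepnet_config(
    preset = "tiny", input_len = 60, lstm_hidden = 5L, fc_hidden = 7L,
    input_vm = FALSE,
    stem = list(`in` = 3L, out = 4L, k = 5L, stride = 3L),
    blocks = list(list(`in` = 4L, out = 6L, k = 3L, stride = 2L)),
    seed = seed
  )
}

test_that("forward pass satisfies the [batch x sequence x classes] shape contract", {
  cfg <- sleepnet_config("tiny", seed = 1)
  m <- build_sleepnet(cfg)
  set.seed(1)
  X <- array(rnorm(3 * 900 * 8, 0, 0.05), dim = c(3, 900, 8))
  probs <- actisleep:::sleepnet_forward(m, X, 2L, 4L)
  expect_equal(dim(probs), c(5, 8)) # 2 x 4 sequences flattened, 5 classes
  expect_equal(colSums(probs), rep(1, 8), tolerance = 1e-6)
  expect_true(all(probs >= 0))

  # the large preset builds and honours the same contract
  cfg17 <- sleepnet_config("resnet17", seed = 1)
  m17 <- build_sleepnet(cfg17)
  expect_equal(length(cfg17$blocks), 8) # stem + 16 block convs = 17 layers
  p17 <- actisleep:::sleepnet_forward(m17, X[, , 1:2, drop = FALSE], 1L, 2L)
  expect_equal(dim(p17), c(5, 2))
})

test_that("builds are reproducible under the config seed", {
  cfg <- sleepnet_config("tiny", seed = 7)
  m1 <- build_sleepnet(cfg)
  m2 <- build_sleepnet(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_sleepnet(sleepnet_config("tiny", seed = 8))
  expect_false(identical(m1$params$stem_W, m3$params$stem_W))
})

test_that("parameter count equals the closed-form layer-by-layer sum", {
  cfg <- sleepnet_config("tiny", seed = 1)
  m <- build_sleepnet(cfg)
  # independent arithmetic: conv W + b, BN gamma + beta, projection
  # shortcuts, LSTM gate matrices, FC layers
  conv <- function(ci, co, k) co * ci * k + co
  bn <- function(c) 2 * c
  expected <- conv(4, 8, 7) # stem (3 axes + vector-magnitude channel)
  chans <- c(8, 16, 32)
  for (i in 1:2) {
    ci <- chans[i]; co <- chans[i + 1]
    expected <- expected + bn(ci) + conv(ci, co, 5) + bn(co) +
      conv(co, co, 5) + conv(ci, co, 1)
  }
  expected <- expected + bn(32)
  H <- 24
  expected <- expected + 2 * (4 * H * 32 + 4 * H * H + 4 * H) # bi-LSTM
  expected <- expected + 32 * (2 * H) + 32 + 5 * 32 + 5       # FC head
  expect_equal(count_params(m), expected)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_check_cfg()
  m <- build_sleepnet(cfg)
  set.seed(7)
  B <- 2L; S <- 3L; N <- B * S
  X <- array(rnorm(3 * 60 * N), dim = c(3, 60, N))
  y <- sample(0:4, N, replace = TRUE)
  cw <- runif(5, 0.5, 2)
  rs0 <- m$run_stats
  out <- actisleep:::cpp_sleepnet_pass(X, y, m$params, cfg, rs0, cw,
                                       B, S, TRUE, TRUE, 0)
  g <- out$grads
  set.seed(1)
  h <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- actisleep:::cpp_sleepnet_pass(X, y, pp, cfg, rs0, cw, B, S,
                                          TRUE, FALSE, 0)$loss
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - h
      lm <- actisleep:::cpp_sleepnet_pass(X, y, pm, cfg, rs0, cw, B, S,
                                          TRUE, FALSE, 0)$loss
      fd <- (lp - lm) / (2 * h)
      an <- g[[nm]][i]
      ok <- abs(fd - an) < 1e-8 ||
        abs(fd - an) / max(abs(fd), abs(an)) < 1e-4
      expect_true(ok, info = sprintf("%s[%d]: fd=%g analytic=%g", nm, i,
                                     fd, an))
    }
  }
})

test_that("self-supervision gradients match finite differences", {
  cfg <- tiny_check_cfg()
  m <- build_sleepnet(cfg, with_ssl_heads = TRUE, n_ssl_tasks = 3L)
  set.seed(8)
  N <- 6L
  X <- array(rnorm(3 * 60 * N), dim = c(3, 60, N))
  yl <- matrix(rbinom(3 * N, 1, 0.5), 3, N)
  rs0 <- m$run_stats
  out <- actisleep:::cpp_ssl_pass(X, yl, m$params, cfg, rs0, TRUE, TRUE)
  g <- out$grads
  set.seed(2)
  h <- 1e-5
  for (nm in c("ssl_W", "ssl_b", "stem_W", "b1_W1", "final_bn_g")) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- actisleep:::cpp_ssl_pass(X, yl, pp, cfg, rs0, TRUE, FALSE)$loss
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - h
      lm <- actisleep:::cpp_ssl_pass(X, yl, pm, cfg, rs0, TRUE, FALSE)$loss
      fd <- (lp - lm) / (2 * h)
      an <- g[[nm]][i]
      ok <- abs(fd - an) < 1e-8 ||
        abs(fd - an) / max(abs(fd), abs(an)) < 1e-4
      expect_true(ok, info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("transformation tasks preserve shape and have the stated algebra", {
  set.seed(3)
  w <- matrix(rnorm(3 * 900), 3)
  # double time reversal is the identity
  expect_identical(
    actisleep:::transform_time_reversal(
      actisleep:::transform_time_reversal(w)), w)
  # identity permutation leaves the window unchanged
  expect_identical(
    actisleep:::transform_segment_permutation(w, 4L, perm = 1:4), w)
  # non-identity permutation changes it but keeps shape
  wp <- actisleep:::transform_segment_permutation(w, 4L, perm = c(2, 1, 4, 3))
  expect_equal(dim(wp), dim(w))
  expect_false(identical(wp, w))
  # warp resamples back to the original length and stays finite
  ww <- actisleep:::transform_time_warp(w, 4L, 0.3)
  expect_equal(dim(ww), dim(w))
  expect_true(all(is.finite(ww)))

  # apply_ssl_transform: output contract and label bookkeeping
  set.seed(4)
  tr <- apply_ssl_transform(w, ssl_task_config())
  expect_equal(dim(tr$window), c(3, 900))
  expect_true(all(is.finite(tr$window)))
  expect_named(tr$labels, c("time_reversal", "segment_permutation",
                            "time_warp"))
  expect_true(all(tr$labels %in% c(0, 1)))
  # deterministic under a fixed RNG state
  set.seed(4)
  tr2 <- apply_ssl_transform(w, ssl_task_config())
  expect_identical(tr, tr2)

  expect_error(ssl_task_config(character(0)))
})

test_that("stage prediction is window-restricted, normalised and deterministic", {
  night <- make_night("S1", 1, n_epochs = 40)
  cfg <- sleepnet_config("tiny", seed = 1)
  m <- build_sleepnet(cfg)
  win <- list(start = night$hypnogram$epoch_start[5],
              end = night$hypnogram$epoch_start[5] + 20 * 30)
  pr <- predict_stages(m, night$epochs, win)
  expect_equal(nrow(pr), 20)
  expect_equal(rowSums(as.matrix(pr[, c("p_W", "p_N1", "p_N2", "p_N3", "p_R")])),
               rep(1, 20), tolerance = 1e-6)
  pr2 <- predict_stages(m, night$epochs, win)
  expect_identical(pr, pr2)
  expect_error(predict_stages(m, night$epochs,
                              list(start = win$start + 86400,
                                   end = win$end + 86400)),
               "no wear epochs")
})

test_that("fold leakage is rejected", {
  nights <- make_cohort_nights(4, 1, n_epochs = 20)
  m <- build_sleepnet(sleepnet_config("tiny", seed = 1, max_epochs = 1))
  bad_folds <- data.frame(subject_id = c("S01", "S01", "S02", "S03", "S04"),
                          fold = c(0, 1, 0, 1, 0))
  expect_error(train_sleepnet(m, nights, folds = bad_folds), "leakage")
})
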