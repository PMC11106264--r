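# Agreement battery: confusion matrices, chance-corrected metrics,
# Bland-Altman, folds, stratified reports.

random_cm <- function(K) {
  matrix(rpois(K * K, lambda = sample(1:30, 1)) +
           diag(sample(0:50, K, replace = TRUE)), K, K)
}

test_that("confusion matrices count true-by-predicted pairs", {
  cm <- confusion(c("W", "W", "R", "NREM"), c("W", "R", "R", "NREM"),
                  "three_class")
  expect_equal(cm["W", "W"], 1L)
  expect_equal(cm["W", "R"], 1L)
  expect_equal(cm["R", "R"], 1L)
  expect_equal(cm["NREM", "NREM"], 1L)
  expect_equal(sum(cm), 4L)

  ident <- confusion(rep(STAGES5, 3), rep(STAGES5, 3), "five_class")
  expect_true(all(ident[upper.tri(ident)] == 0 & ident[lower.tri(ident)] == 0))

  expect_error(confusion("W", c("W", "R"), "three_class"), "lengths")
  expect_error(confusion("W", "X", "three_class"), "alphabet")
})

test_that("worked 2x2 example reproduces hand-computed metrics", {
  cm <- matrix(c(40, 10, 5, 45), 2, byrow = TRUE,
               dimnames = list(true = c("a", "b"), pred = c("a", "b")))
  m <- agreement_metrics(cm)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(m$kappa, 0.70, tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, 0.85, tolerance = 1e-12)
  expect_equal(m$macro_f1, 0.8496, tolerance = 5e-5)

  perfect <- agreement_metrics(diag(5) * 10)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  # constant prediction over balanced truth: chance level
  const <- matrix(c(50, 0, 50, 0), 2, byrow = TRUE)
  expect_equal(agreement_metrics(const)$kappa, 0, tolerance = 1e-12)
})

test_that("metrics match the brute-force oracle on random confusion matrices", {
  set.seed(101)
  for (i in 1:60) {
    K <- sample(2:5, 1)
    cm <- random_cm(K)
    if (sum(cm) == 0) next
    got <- agreement_metrics(cm)
    want <- oracle_metrics(cm)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
    expect_equal(got$balanced_accuracy, want$balanced_accuracy,
                 tolerance = 1e-12)
    expect_equal(got$per_class$sensitivity, want$sens, tolerance = 1e-12)
    expect_equal(got$per_class$specificity, want$spec, tolerance = 1e-12)
    expect_equal(got$per_class$precision, want$prec, tolerance = 1e-12)
  }
})

test_that("kappa is invariant to simultaneous row/column permutation", {
  set.seed(5)
  for (i in 1:20) {
    cm <- random_cm(4)
    p <- sample(4)
    expect_equal(agreement_metrics(cm)$kappa,
                 agreement_metrics(cm[p, p])$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate marginals flag kappa as undefined", {
  cm <- matrix(c(10, 0, 0, 0), 2, byrow = TRUE) # everything one class
  m <- agreement_metrics(cm)
  expect_false(m$kappa_defined)
  expect_true(is.na(m$kappa))
})

test_that("subject-level report averages per-subject metrics with between-subject SD", {
  # one subject, perfect predictions -> 1.0 +/- 0
  r1 <- subject_level_report(rep(c("W", "SLEEP"), 10), rep(c("W", "SLEEP"), 10),
                             rep("A", 20), "two_class")
  expect_equal(r1$subject_mean$mean[r1$subject_mean$metric == "macro_f1"], 1)
  expect_equal(r1$subject_mean$sd[r1$subject_mean$metric == "macro_f1"], 0)

  # two subjects engineered to per-subject F1 of 0.6 and 0.8
  # F1 = 2tp/(2tp+fp+fn): subject A 3/(3+2+2)=6/10=0.6 per class
  tA <- c(rep("W", 5), rep("SLEEP", 5))
  pA <- c(rep("W", 3), rep("SLEEP", 2), rep("W", 2), rep("SLEEP", 3))
  f1A <- agreement_metrics(confusion(tA, pA, "two_class"))$macro_f1
  tB <- c(rep("W", 5), rep("SLEEP", 5))
  pB <- c(rep("W", 4), "SLEEP", "W", rep("SLEEP", 4))
  f1B <- agreement_metrics(confusion(tB, pB, "two_class"))$macro_f1
  expect_equal(f1A, 0.6)
  expect_equal(f1B, 0.8)
  r2 <- subject_level_report(c(tA, tB), c(pA, pB),
                             rep(c("A", "B"), each = 10), "two_class")
  sm <- r2$subject_mean
  expect_equal(sm$mean[sm$metric == "macro_f1"], 0.7)
  expect_equal(sm$sd[sm$metric == "macro_f1"], sd(c(0.6, 0.8)),
               tolerance = 1e-12)
  # pooled metrics reported separately and labelled
  expect_s3_class(r2$pooled, "agreement_report")
  expect_equal(unname(r2$level["pooled"]), "epoch_pooled")

  # single-class subject excluded from the kappa summary
  r3 <- subject_level_report(c("W", "W", "W", "SLEEP", "W"),
                             c("W", "SLEEP", "W", "SLEEP", "W"),
                             c("A", "A", "A", "B", "B"), "two_class")
  expect_true(r3$per_subject$single_class[r3$per_subject$subject_id == "A"])
  expect_equal(r3$subject_mean$n_subjects[r3$subject_mean$metric == "kappa"], 1)
})

test_that("Bland-Altman closed forms and sign convention", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3), "tst")
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_low, 0)
  expect_equal(ident$loa_high, 0)

  ba <- bland_altman(c(0, 0), c(4, 6), "tst")
  expect_equal(ba$bias, 5)
  expect_equal(ba$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, 5 - 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 5 + 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(ba$loa_low, 3), 2.228)
  expect_equal(round(ba$loa_high, 3), 7.772)

  # estimate above reference => positive bias (overestimation)
  over <- bland_altman(reference_values = c(5, 5), estimated_values = c(6, 7))
  expect_gt(over$bias, 0)

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman recovers the generating Gaussian within standard error", {
  set.seed(77)
  n <- 500
  ref <- rnorm(n, 6, 1)
  d <- rnorm(n, 0.5, 0.8)
  ba <- bland_altman(ref, ref + d, "sim")
  se_bias <- 0.8 / sqrt(n)
  expect_lt(abs(ba$bias - 0.5), 2 * se_bias)
  se_sd <- 0.8 / sqrt(2 * (n - 1))
  expect_lt(abs(ba$sd_diff - 0.8), 2 * se_sd)
})

test_that("fold assignment is a balanced, seeded partition", {
  ids <- sprintf("S%02d", 1:10)
  f <- make_folds(ids, k = 5, seed = 3)
  expect_setequal(f$subject_id, ids)
  expect_equal(as.numeric(table(f$fold)), rep(2, 5))
  expect_identical(f, make_folds(ids, k = 5, seed = 3))
  expect_false(identical(f$fold, make_folds(ids, k = 5, seed = 4)$fold))
  expect_error(make_folds(ids[1:3], k = 5), "fewer subjects")
})

test_that("stratified report splits per-subject metrics by stratum", {
  # two strata with different prediction noise levels
  set.seed(9)
  truths <- list(); preds <- list(); subj <- list()
  strata <- c()
  for (i in 1:8) {
    sid <- sprintf("S%d", i)
    noise <- if (i <= 4) 0.05 else 0.4
    tr <- sample(c("W", "SLEEP"), 200, replace = TRUE)
    pr <- ifelse(runif(200) < noise, sample(c("W", "SLEEP"), 200, TRUE), tr)
    truths[[i]] <- tr; preds[[i]] <- pr; subj[[i]] <- rep(sid, 200)
    strata[sid] <- if (i <= 4) "clean" else "noisy"
  }
  rep <- subject_level_report(unlist(truths), unlist(preds), unlist(subj),
                              "two_class")
  st <- stratified_report(rep$per_subject, strata, metric = "kappa")
  expect_equal(sum(st$n), 8)
  expect_gt(st$mean[st$stratum == "clean"],
            st$mean[st$stratum == "noisy"])

  # single stratum equals the plain subject-level mean
  one <- stratified_report(rep$per_subject,
                           setNames(rep("all", 8), names(strata)), "kappa")
  expect_equal(one$mean,
               rep$subject_mean$mean[rep$subject_mean$metric == "kappa"],
               tolerance = 1e-12)

  expect_error(stratified_report(rep$per_subject, strata[1:3]), "unknown")
})
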