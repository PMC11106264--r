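# Time-in-bed detection: merging, overnight selection, forest + HMM
# detector, and the random-forest stage baseline.

test_that("windows within 60 min are merged, larger gaps are not", {
  w <- data.frame(
    start = utc(c("2024-01-01 22:00:00", "2024-01-01 23:30:00")),
    end = utc(c("2024-01-01 23:00:00", "2024-01-02 06:00:00")),
    source = "detected"
  )
  m <- merge_windows(w, 60)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, w$start[1])
  expect_equal(m$end, w$end[2])
  expect_equal(m$source, "merged")

  # 61-min gap stays separate
  w61 <- data.frame(
    start = utc(c("2024-01-01 22:00:00", "2024-01-02 00:01:00")),
    end = utc(c("2024-01-01 23:00:00", "2024-01-02 06:00:00")),
    source = "detected"
  )
  expect_equal(nrow(merge_windows(w61, 60)), 2)

  # transitive closure over a chain of 45-min gaps
  chain <- data.frame(
    start = utc(c("2024-01-01 20:00:00", "2024-01-01 21:45:00",
                  "2024-01-01 23:30:00")),
    end = utc(c("2024-01-01 21:00:00", "2024-01-01 22:45:00",
                "2024-01-02 06:00:00")),
    source = "detected"
  )
  m3 <- merge_windows(chain, 60)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$start, chain$start[1])
  expect_equal(m3$end, chain$end[3])

  # overlapping inputs are merged; idempotent and order-invariant
  ovl <- chain[c(3, 1, 2), ]
  m4 <- merge_windows(ovl, 60)
  expect_equal(m4$start, m3$start)
  expect_equal(merge_windows(m4, 60)$end, m4$end)
  expect_equal(nrow(merge_windows(data.frame(start = utc(character()),
                                             end = utc(character())))), 0)
})

test_that("overnight selection takes the longest window per noon-to-noon interval", {
  w <- data.frame(
    start = utc(c("2024-01-01 23:00:00", "2024-01-02 14:00:00")),
    end = utc(c("2024-01-02 06:00:00", "2024-01-02 15:00:00"))
  )
  sel <- select_overnight_window(w)
  # both midpoints fall in the noon(Jan 1) -> noon(Jan 2) and the next
  # interval respectively: the 7-h window belongs to Jan 1's night
  expect_equal(sel$night_date[1], as.Date("2024-01-01"))
  expect_equal(sel$duration_h[1], 7)
  # the nap is the only (and thus longest) window of Jan 2's interval
  expect_equal(nrow(sel), 2)

  # same interval: longest wins
  w2 <- data.frame(
    start = utc(c("2024-01-01 23:00:00", "2024-01-02 02:00:00")),
    end = utc(c("2024-01-02 00:30:00", "2024-01-02 08:00:00"))
  )
  sel2 <- select_overnight_window(w2)
  expect_equal(nrow(sel2), 1)
  expect_equal(sel2$start, w2$start[2])

  # equal lengths: earliest start wins (documented tie-break)
  w3 <- data.frame(
    start = utc(c("2024-01-02 03:00:00", "2024-01-01 22:00:00")),
    end = utc(c("2024-01-02 05:00:00", "2024-01-02 00:00:00"))
  )
  sel3 <- select_overnight_window(w3)
  expect_equal(nrow(sel3), 1)
  expect_equal(sel3$start, utc("2024-01-01 22:00:00"))

  expect_equal(nrow(select_overnight_window(w[0, ])), 0)
})

test_that("diary-trained detector recovers the bed interval on held-out nights", {
  subs <- lapply(1:3, function(i) {
    simulate_subject(sprintf("S%d", i), 2, seed = 40 + i,
                     wear_start_hour = 20, wear_end_hour = 10)
  })
  feats <- list(); labs <- list(); grp <- list()
  for (s in subs) {
    for (n in seq_along(s$recordings)) {
      pp <- preprocess_recording(s$recordings[[n]])
      f <- extract_features(pp$epochs)
      feats[[length(feats) + 1L]] <- f
      labs[[length(labs) + 1L]] <- diary_epoch_labels(f$epoch_start, s$diary,
                                                      s$subject_id)
      grp[[length(grp) + 1L]] <- rep(paste(s$subject_id, n), nrow(f))
    }
  }
  # train on subjects 1-2, evaluate on subject 3
  tr <- 1:4
  te <- 5:6
  Ftr <- do.call(rbind, feats[tr])
  model <- fit_window_model(Ftr, unlist(labs[tr]), groups = unlist(grp[tr]),
                            seed = 1)
  expect_equal(rowSums(model$transition), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # held-out epoch accuracy of the decoded path
  for (i in te) {
    w <- predict_time_in_bed(model, feats[[i]], feats[[i]]$epoch_start)
    w <- merge_windows(w)
    sel <- select_overnight_window(w)
    expect_equal(nrow(sel), 1)
    night <- i - 4L
    hyp <- subs[[3]]$hypnograms[[night]]
    tru_s <- hyp$epoch_start[1]
    tru_e <- hyp$epoch_start[nrow(hyp)] + 30
    inter <- max(0, min(as.numeric(sel$end), as.numeric(tru_e)) -
                   max(as.numeric(sel$start), as.numeric(tru_s)))
    union <- max(as.numeric(sel$end), as.numeric(tru_e)) -
      min(as.numeric(sel$start), as.numeric(tru_s))
    expect_gt(inter / union, 0.8)
    # decoded in-bed state vs diary labels: held-out accuracy > 0.95
    in_bed_pred <- feats[[i]]$epoch_start >= sel$start &
      feats[[i]]$epoch_start < sel$end
    expect_gt(mean(in_bed_pred == labs[[i]]), 0.95)
  }

  # determinism under the seed
  m2 <- fit_window_model(Ftr, unlist(labs[tr]), groups = unlist(grp[tr]),
                         seed = 1)
  w1 <- predict_time_in_bed(model, feats[[5]], feats[[5]]$epoch_start)
  w2 <- predict_time_in_bed(m2, feats[[5]], feats[[5]]$epoch_start)
  expect_identical(w1, w2)

  expect_error(fit_window_model(Ftr, rep(TRUE, nrow(Ftr))), "single class")
  expect_equal(nrow(predict_time_in_bed(model, Ftr[0, ], utc(character()))), 0)
})

test_that("random-forest stage baseline separates sleep from wake, collapses to chance when shuffled", {
  nights <- make_cohort_nights(6, 1, n_epochs = 100)
  feats <- list(); stages <- list(); subjects <- list()
  for (nt in nights) {
    f <- extract_features(nt$epochs)
    feats[[length(feats) + 1L]] <- f
    stages[[length(stages) + 1L]] <- as.character(nt$hypnogram$stage)
    subjects[[length(subjects) + 1L]] <- rep(nt$subject_id, nrow(f))
  }
  F <- do.call(rbind, feats)
  S <- unlist(stages)
  id <- unlist(subjects)

  pred <- rf_stage_baseline(F, S, id, k = 3, seed = 7)
  cm2 <- confusion(collapse_stages(S, "two_class"),
                   collapse_stages(as.character(pred), "two_class"),
                   "two_class")
  expect_gt(agreement_metrics(cm2)$kappa, 0.7)

  # determinism
  pred2 <- rf_stage_baseline(F, S, id, k = 3, seed = 7)
  expect_identical(pred, pred2)

  # label shuffling: mean |kappa| < 0.05 over 5 seeds
  kappas <- vapply(1:5, function(s) {
    set.seed(s)
    Sp <- sample(S)
    p <- rf_stage_baseline(F, Sp, id, k = 3, seed = s)
    agreement_metrics(confusion(Sp, as.character(p), "five_class"))$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas)), 0.05)
})
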