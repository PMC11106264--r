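# Validation battery: confusion matrices, chance-corrected agreement,
# Bland-Altman limits of agreement, subject-wise folds and stratified
# reports.

scheme_levels <- function(scheme) {
  switch(scheme,
    five_class = STAGES5,
    three_class = STAGES3,
    two_class = STAGES2,
    stop("unknown scheme: ", scheme)
  )
}

#' Confusion matrix
#'
#' @param true_labels,pred_labels equal-length label vectors in the
#'   scheme's alphabet.
#' @param scheme `"five_class"`, `"three_class"` or `"two_class"`.
#' @return a K x K integer matrix of class `confusion_matrix`; entry
#'   `(i, j)` counts epochs of true class `i` predicted as class `j`.
#' @export
confusion <- function(true_labels, pred_labels, scheme = "five_class") {
  lv <- scheme_levels(scheme)
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels)) {
    stop("true and predicted label sequences have different lengths")
  }
  bad <- setdiff(unique(c(true_labels, pred_labels)), lv)
  if (length(bad) > 0L) stop("labels outside scheme alphabet: ", paste(bad, collapse = ", "))
  cm <- table(factor(true_labels, levels = lv), factor(pred_labels, levels = lv))
  cm <- unclass(matrix(as.integer(cm), nrow = length(lv),
                       dimnames = list(true = lv, pred = lv)))
  class(cm) <- c("confusion_matrix", class(cm))
  attr(cm, "scheme") <- scheme
  cm
}

#' Agreement metrics from a confusion matrix
#'
#' Cohen's kappa `(p_o - p_e) / (1 - p_e)` with the chance agreement `p_e`
#' from the marginals, macro F1 (unweighted mean of per-class F1),
#' balanced accuracy (mean per-class recall), and per-class sensitivity,
#' specificity and precision. Per-class F1 of a class absent from both
#' truth and prediction is undefined and excluded from the macro mean.
#'
#' @param cm a K x K count matrix (rows = truth), e.g. from [confusion()].
#' @return a list of class `agreement_report` with fields `kappa`,
#'   `macro_f1`, `balanced_accuracy`, `accuracy`, `per_class`
#'   (data.frame), `n`, `kappa_defined`.
#' @export
agreement_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  storage.mode(cm) <- "double"
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix is empty")
  K <- nrow(cm)
  rowm <- rowSums(cm)
  colm <- colSums(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowm * colm) / n^2
  kappa_defined <- abs(1 - p_e) > 1e-12
  kappa <- if (kappa_defined) (p_o - p_e) / (1 - p_e) else NA_real_

  tp <- diag(cm)
  fn <- rowm - tp
  fp <- colm - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(rowm > 0, tp / rowm, NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  prec <- ifelse(colm > 0, tp / colm, NA_real_)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(K)),
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    support = rowm
  )
  structure(
    list(
      kappa = kappa, kappa_defined = kappa_defined,
      macro_f1 = mean(f1, na.rm = TRUE),
      balanced_accuracy = mean(sens, na.rm = TRUE),
      accuracy = p_o, per_class = per_class, n = n
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n=%d kappa=%.3f macroF1=%.3f balanced_acc=%.3f acc=%.3f\n",
    x$n, x$kappa, x$macro_f1, x$balanced_accuracy, x$accuracy
  ))
  invisible(x)
}

#' Subject-level agreement report
#'
#' Metrics are computed per subject, then summarised across subjects as
#' mean +/- between-subject sample SD; the pooled (all-epoch) metrics are
#' reported alongside and labelled. Subjects whose truth contains a single
#' class have undefined kappa and are excluded from the kappa summary.
#'
#' @param true_labels,pred_labels label vectors over all epochs.
#' @param subjects subject identifier per epoch.
#' @param scheme label scheme.
#' @return list with `subject_mean` (data.frame metric/mean/sd/n),
#'   `per_subject` (data.frame), `pooled` (an `agreement_report`).
#' @export
subject_level_report <- function(true_labels, pred_labels, subjects,
                                 scheme = "five_class") {
  stopifnot(length(true_labels) == length(pred_labels),
            length(subjects) == length(true_labels))
  ids <- unique(subjects)
  rows <- lapply(ids, function(sid) {
    sel <- subjects == sid
    m <- agreement_metrics(confusion(true_labels[sel], pred_labels[sel], scheme))
    data.frame(subject_id = sid, kappa = m$kappa, macro_f1 = m$macro_f1,
               balanced_accuracy = m$balanced_accuracy, accuracy = m$accuracy,
               n_epochs = m$n,
               single_class = length(unique(true_labels[sel])) < 2L)
  })
  per_subject <- do.call(rbind, rows)
  summarise <- function(v, drop = rep(FALSE, length(v))) {
    v <- v[!drop & !is.na(v)]
    c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0, n = length(v))
  }
  met <- rbind(
    kappa = summarise(per_subject$kappa, per_subject$single_class),
    macro_f1 = summarise(per_subject$macro_f1),
    balanced_accuracy = summarise(per_subject$balanced_accuracy),
    accuracy = summarise(per_subject$accuracy)
  )
  subject_mean <- data.frame(metric = rownames(met), mean = met[, "mean"],
                             sd = met[, "sd"], n_subjects = met[, "n"],
                             row.names = NULL)
  pooled <- agreement_metrics(confusion(true_labels, pred_labels, scheme))
  list(subject_mean = subject_mean, per_subject = per_subject, pooled = pooled,
       level = c(summary = "subject_mean", pooled = "epoch_pooled"))
}

#' Bland-Altman agreement
#'
#' Differences are estimate minus reference, so a positive bias means the
#' method overestimates the parameter. Limits of agreement are
#' `bias +/- 1.96 * sd(differences)` (normal-theory 95% limits).
#'
#' @param reference_values,estimated_values paired per-night values
#'   (length >= 2).
#' @param parameter parameter name carried in the result.
#' @return a list of class `bland_altman_result` with `parameter`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_nights`, `differences`, `means`.
#' @export
bland_altman <- function(reference_values, estimated_values, parameter = "") {
  stopifnot(length(reference_values) == length(estimated_values))
  ok <- !is.na(reference_values) & !is.na(estimated_values)
  d <- estimated_values[ok] - reference_values[ok]
  if (length(d) < 2L) stop("Bland-Altman needs at least 2 paired values")
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(parameter = parameter, bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         n_nights = length(d), differences = d,
         means = (estimated_values[ok] + reference_values[ok]) / 2),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> %s: bias=%.2f (95%% LoA %.2f to %.2f), n=%d\n",
              x$parameter, x$bias, x$loa_low, x$loa_high, x$n_nights))
  invisible(x)
}

#' Subject-wise fold assignment
#'
#' Balanced partition of subjects into k folds (fold sizes differ by at
#' most one), deterministic under the seed.
#'
#' @param subject_ids vector of unique subject identifiers.
#' @param k number of folds.
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `fold` (0-based index).
#' @export
make_folds <- function(subject_ids, k = 5, seed = 1L) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample(subject_ids)
  fold <- rep(seq_len(k) - 1L, length.out = n)
  out <- data.frame(subject_id = perm, fold = fold)
  out <- out[match(subject_ids, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified performance report
#'
#' Per-stratum mean +/- SD of per-subject metrics.
#'
#' @param per_subject data.frame from [subject_level_report()] (field
#'   `per_subject`).
#' @param strata named vector mapping `subject_id` to stratum label.
#' @param metric which metric column to summarise.
#' @param min_n strata with fewer subjects are flagged.
#' @return data.frame with `stratum`, `mean`, `sd`, `n`, `flagged`.
#' @export
stratified_report <- function(per_subject, strata, metric = "kappa",
                              min_n = 2L) {
  lab <- strata[as.character(per_subject$subject_id)]
  if (anyNA(lab)) stop("unknown stratum for subject(s): ",
                       paste(per_subject$subject_id[is.na(lab)], collapse = ", "))
  vals <- per_subject[[metric]]
  out <- do.call(rbind, lapply(unique(lab), function(s) {
    v <- vals[lab == s & !is.na(vals)]
    data.frame(stratum = s, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               n = sum(lab == s), flagged = sum(lab == s) < min_n)
  }))
  rownames(out) <- NULL
  out
}
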