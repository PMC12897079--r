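#' Patient-level k-fold partition
#'
#' Assigns patients to folds so that no patient's slices can ever cross the
#' train/test boundary (the partition is the unit of data leakage control).
#' With `stratify = TRUE` fold assignment balances the class labels, keeping
#' per-stratum fold sizes within one of each other.
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param labels Class labels (0/1) aligned with `patient_ids`.
#' @param k Number of folds (default 5); at most the number of patients.
#' @param seed Seed for the shuffle.
#' @param stratify Stratify folds by label (default TRUE).
#' @return An object of class `fold_partition`: data.frame with `patient_id`,
#'   `label`, `fold`.
#' @export
partition_patients <- function(patient_ids, labels, k = 5L, seed = NULL,
                               stratify = TRUE) {
  if (anyDuplicated(patient_ids)) stopf("`patient_ids` must be unique")
  if (length(labels) != length(patient_ids))
    stopf("`labels` must align with `patient_ids`")
  k <- check_count(k, "k")
  if (k > length(patient_ids))
    stopf("k = %d exceeds the number of patients (%d)", k, length(patient_ids))
  fold <- integer(length(patient_ids))
  with_seed(seed, {
    groups <- if (stratify) split(seq_along(patient_ids), labels)
              else list(seq_along(patient_ids))
    totals <- integer(k)
    for (g in groups) {
      shuffled <- g[sample.int(length(g))]
      base <- length(g) %/% k
      extra <- length(g) %% k
      counts <- rep(base, k)
      if (extra > 0) {
        # give remainders to the currently smallest folds so overall fold
        # sizes stay within one of each other across strata
        ord <- order(totals + stats::runif(k))   # random tie-break
        counts[ord[seq_len(extra)]] <- base + 1L
      }
      fold[shuffled] <- rep(seq_len(k), counts)
      totals <- totals + counts
    }
  })
  structure(data.frame(patient_id = patient_ids, label = labels, fold = fold,
                       stringsAsFactors = FALSE),
            k = k, class = c("fold_partition", "data.frame"))
}

#' Confusion matrix with AME (label 1) as the positive class
#'
#' @param truth True labels (0/1).
#' @param predicted Predicted labels (0/1).
#' @return An object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stopf("length mismatch")
  structure(list(tp = sum(truth == 1 & predicted == 1),
                 tn = sum(truth == 0 & predicted == 0),
                 fp = sum(truth == 0 & predicted == 1),
                 fn = sum(truth == 1 & predicted == 0)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the F1 score (harmonic mean of
#' precision and recall). A ratio with a zero denominator is reported as `NA`
#' with a warning, never silently as 0.
#'
#' Note on specificity: it is implemented in its standard form `TN/(TN+FP)`,
#' the quantity whose complement is the ROC false-positive axis.
#'
#' @param cm A [confusion_matrix()] (or list with tp/tn/fp/fn counts).
#' @param level Optional tag, `"slice"` or `"patient"`, carried in the output.
#' @return List of class `metrics_report`.
#' @export
classification_metrics <- function(cm, level = NULL) {
  tot <- cm$tp + cm$tn + cm$fp + cm$fn
  if (tot == 0) stopf("degenerate confusion matrix: no observations")
  ratio <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (zero denominator)", what),
                            call. = FALSE); return(NA_real_) }
    num / den
  }
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (cm$tp + cm$tn) / tot, precision = precision,
                 recall = recall,
                 specificity = ratio(cm$tn, cm$tn + cm$fp, "specificity"),
                 f1 = f1, level = level),
            class = "metrics_report")
}

#' Patient-level soft voting
#'
#' Aggregates a patient's slice probabilities by their arithmetic mean; the
#' predicted class is 1 (AME) when the mean reaches the threshold
#' (ties at the threshold go to class 1).
#'
#' @param slice_probs Numeric vector of the patient's slice probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `probability` and `class`.
#' @export
patient_soft_vote <- function(slice_probs, threshold = 0.5) {
  if (length(slice_probs) < 1L) stopf("no slice probabilities supplied")
  if (any(slice_probs < 0 | slice_probs > 1))
    stopf("probabilities must lie in [0, 1]")
  p <- mean(slice_probs)
  list(probability = p, class = as.integer(p >= threshold))
}

# DeLong structural components ("placements") via midranks.
# V10[i]: fraction of negatives the i-th positive outranks (ties = 1/2);
# V01[j]: fraction of positives the j-th negative is outranked by.
.delong_placements <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stopf("both classes must be present to compute AUC")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' ROC AUC with DeLong variance
#'
#' The AUC is the Mann-Whitney pair statistic (ties counted one half),
#' computed via midranks; its variance is estimated with DeLong's structural
#' components method, enabling confidence statements and paired comparisons.
#'
#' @param labels 0/1 labels (1 = AME, the positive class).
#' @param scores Classifier scores or probabilities for class 1.
#' @return An object of class `roc_result`: list with `auc`,
#'   `delong_variance`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stopf("labels/scores length mismatch")
  pl <- .delong_placements(labels, scores)
  v <- if (pl$m > 1 && pl$n > 1)
    stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n else NA_real_
  structure(list(auc = pl$auc, delong_variance = v,
                 n_pos = pl$m, n_neg = pl$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (DeLong SE %.4f; %d pos / %d neg)\n", x$auc,
              sqrt(x$delong_variance), x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same cases. The
#' difference is normalized by the DeLong covariance of the paired structural
#' components and referred to the standard normal (two-sided).
#'
#' @param labels Shared 0/1 labels.
#' @param scores_a,scores_b Paired score vectors on the identical cases.
#' @return List with `auc_a`, `auc_b`, `z`, `p` and `var_diff`. If the
#'   variance of the difference is exactly zero the pair is numerically
#'   degenerate: `p` is 1 when the AUCs agree, otherwise `NA` with a warning.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stopf("scores must be paired with labels on identical cases")
  pa <- .delong_placements(labels, scores_a)
  pb <- .delong_placements(labels, scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0,
                                    p = 1, var_diff = var_diff))
    warning("zero DeLong variance with unequal AUCs: test is numerically degenerate",
            call. = FALSE)
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = NA_real_, p = NA_real_,
                var_diff = var_diff))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction (the form that
#' reproduces standard cohort-table p-values), with
#' `df = (rows - 1) * (cols - 1)` and the upper-tail chi-square p-value. All
#' expected counts must be positive.
#'
#' @param table Matrix of non-negative counts (categories x groups).
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stopf("counts must be non-negative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stopf("zero expected count: test undefined")
  if (all(table == expected)) {
    # chisq.test is exact here too, but keep the degenerate path explicit
    return(list(statistic = 0,
                df = (nrow(table) - 1) * (ncol(table) - 1), p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided test of location difference. For samples where the smaller group
#' has fewer than 20 observations (and no ties) the exact distribution is
#' used; otherwise the normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (the U statistic of `x`) and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stopf("both samples must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) < 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Patient-level cross-validation of one ROI variant
#'
#' For each fold, trains the backend on the remaining folds (MAPS weighted
#' sampling, the shared augmentation pipeline and schedule) and evaluates the
#' held-out fold with uniform patient batches, reporting confusion-matrix
#' metrics and ROC/AUC at both the slice and the patient level (patient
#' probabilities by soft voting). The held-out fold also serves as the
#' early-stopping validation set, mirroring a k-fold protocol with per-fold
#' validation monitoring.
#'
#' @param data A `slice_dataset` for one variant.
#' @param partition A [partition_patients()] result.
#' @param backend_factory Zero-argument function returning a fresh untrained
#'   backend (one per fold).
#' @param schedule,augment,sampler_level,batch_size Passed to
#'   [train_backend()].
#' @param seed Base seed; fold f trains with `seed + f`.
#' @param keep_backends Keep each fold's trained backend in the result
#'   (default FALSE; they are large).
#' @param verbose Print per-epoch progress.
#' @return An object of class `cv_result`: list with `folds` (per-fold metric
#'   reports and AUCs), `oof` (pooled out-of-fold slice predictions),
#'   `oof_patient` (soft-voted patient predictions) and `summary`
#'   (fold mean and sample SD per metric and level).
#' @export
cross_validate <- function(data, partition,
                           backend_factory = function() cnn_backend(),
                           schedule = lr_schedule(),
                           augment = augment_params(),
                           sampler_level = "patient", batch_size = 16L,
                           seed = 1L, keep_backends = FALSE,
                           verbose = FALSE) {
  k <- attr(partition, "k")
  man <- data$manifest
  missing_pat <- setdiff(unique(man$patient_id), partition$patient_id)
  if (length(missing_pat) > 0)
    stopf("patients missing from the partition: %s",
          paste(missing_pat, collapse = ", "))
  subset_ds <- function(pats) {
    keep <- man$patient_id %in% pats
    m2 <- man[keep, , drop = FALSE]
    structure(list(images = data$images[m2$image_id],
                   manifest = transform(m2, image_id = seq_len(nrow(m2)))),
              class = "slice_dataset")
  }
  folds <- list(); oof <- list(); oof_pat <- list()
  for (f in seq_len(k)) {
    test_pats <- partition$patient_id[partition$fold == f]
    train_pats <- partition$patient_id[partition$fold != f]
    tr <- subset_ds(train_pats); te <- subset_ds(test_pats)
    fit <- train_backend(backend_factory(), tr, te, schedule = schedule,
                         augment = augment, sampler_level = sampler_level,
                         batch_size = batch_size, seed = seed + f,
                         verbose = verbose)
    plan <- uniform_patient_batches(table(te$manifest$patient_id),
                                    seed = seed + f)
    pred <- predict_slices(fit$backend, te, augment = augment, plan = plan)
    pred$fold <- f
    slice_cm <- confusion_matrix(pred$label, as.integer(pred$prob >= 0.5))
    slice_metrics <- classification_metrics(slice_cm, level = "slice")
    slice_roc <- roc_auc(pred$label, pred$prob)
    agg <- do.call(rbind, lapply(split(pred, pred$patient_id), function(d) {
      sv <- patient_soft_vote(d$prob)
      data.frame(patient_id = d$patient_id[1], label = d$label[1],
                 prob = sv$probability, class = sv$class, fold = f,
                 stringsAsFactors = FALSE)
    }))
    pat_cm <- confusion_matrix(agg$label, agg$class)
    pat_metrics <- classification_metrics(pat_cm, level = "patient")
    pat_roc <- roc_auc(agg$label, agg$prob)
    folds[[f]] <- list(fold = f, slice = slice_metrics, patient = pat_metrics,
                       slice_auc = slice_roc, patient_auc = pat_roc,
                       history = fit$history,
                       backend = if (keep_backends) fit$backend)
    oof[[f]] <- pred; oof_pat[[f]] <- agg
  }
  metric_names <- c("accuracy", "precision", "recall", "specificity", "f1")
  summarise <- function(level, auc_field) {
    vals <- sapply(folds, function(x)
      c(unlist(x[[level]][metric_names]), auc = x[[auc_field]]$auc))
    data.frame(level = level, metric = rownames(vals),
               mean = rowMeans(vals), sd = apply(vals, 1, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(folds = folds,
                 oof = do.call(rbind, oof),
                 oof_patient = do.call(rbind, oof_pat),
                 summary = rbind(summarise("slice", "slice_auc"),
                                 summarise("patient", "patient_auc"))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", length(x$folds)))
  s <- x$summary
  for (lev in unique(s$level)) {
    d <- s[s$level == lev, ]
    cat(sprintf("  %s: %s\n", lev,
                paste(sprintf("%s %.3f±%.3f", d$metric, d$mean, d$sd),
                      collapse = "  ")))
  }
  invisible(x)
}
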