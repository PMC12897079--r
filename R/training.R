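#' Train a classifier backend on a slice dataset
#'
#' Fits the backend with MAPS weighted patient sampling, the configured
#' augmentation pipeline and the two-phase learning-rate schedule, monitoring
#' validation accuracy for early stopping. Training and validation sets must
#' come from disjoint patients: any overlap is a data-leakage error and fails
#' hard, because slices of one patient in both sets inflate apparent
#' performance.
#'
#' One epoch makes `N_total` weighted draws (the training set's total image
#' count). The history records per-epoch learning rate, training loss and
#' accuracy (averaged over batches, under augmentation), validation loss and
#' accuracy, and the train-minus-validation accuracy gap monitored against
#' the 0.1 overfitting threshold.
#'
#' @param backend An untrained (or resumed) classifier backend, e.g.
#'   [cnn_backend()].
#' @param train_data,val_data `slice_dataset` objects (see
#'   [preprocess_cohort()]) with disjoint patient sets.
#' @param schedule An [lr_schedule()].
#' @param augment An [augment_params()]; its `target_size` must match the
#'   backend input size.
#' @param sampler_level Passed to [training_sampler()].
#' @param batch_size Minibatch size (default 16).
#' @param seed Seed governing sampling, augmentation and dropout; a fixed
#'   seed reproduces the full history.
#' @param verbose Print one line per epoch.
#' @return List with `backend` (trained) and `history` (data.frame).
#' @export
train_backend <- function(backend, train_data, val_data,
                          schedule = lr_schedule(),
                          augment = augment_params(),
                          sampler_level = c("patient", "image"),
                          batch_size = 16L, seed = 1L, verbose = FALSE) {
  UseMethod("train_backend")
}

#' @export
train_backend.cnn_backend <- function(backend, train_data, val_data,
                                      schedule = lr_schedule(),
                                      augment = augment_params(),
                                      sampler_level = c("patient", "image"),
                                      batch_size = 16L, seed = 1L,
                                      verbose = FALSE) {
  sampler_level <- match.arg(sampler_level)
  if (augment$target_size != backend$input_size)
    stopf("augmentation target_size (%d) must match backend input_size (%d)",
          augment$target_size, backend$input_size)
  tr_pat <- unique(train_data$manifest$patient_id)
  va_pat <- unique(val_data$manifest$patient_id)
  leak <- intersect(tr_pat, va_pat)
  if (length(leak) > 0)
    stopf("data leakage: patient(s) %s appear in both training and validation",
          paste(leak, collapse = ", "))

  counts <- table(train_data$manifest$patient_id)
  w <- maps_weights(stats::setNames(as.integer(counts), names(counts)))
  n_total <- attr(w, "n_total")
  # global image index per (patient, within-patient position)
  by_pat <- split(train_data$manifest$image_id, train_data$manifest$patient_id)

  val_images <- lapply(val_data$images, augment_slice, params = augment,
                       mode = "eval")
  val_y <- val_data$manifest$label

  history <- list()
  best_acc <- -Inf; best_params <- NULL; since_best <- 0L
  with_seed(seed, {
    for (epoch in seq_len(schedule$max_epochs)) {
      lr <- lr_at_epoch(epoch, schedule)
      draws <- training_sampler(w, n_total, level = sampler_level)
      ep_loss <- 0; ep_correct <- 0L
      for (s in seq(1L, n_total, batch_size)) {
        e <- min(n_total, s + batch_size - 1L)
        ids <- mapply(function(p, k) by_pat[[p]][k],
                      draws$patient_id[s:e], draws$image_index[s:e])
        imgs <- lapply(train_data$images[ids], augment_slice,
                       params = augment, mode = "train")
        y <- train_data$manifest$label[ids]
        Xb <- .stack_batch(imgs)
        fw <- .cnn_forward(backend, Xb, train = TRUE, keep = TRUE)
        backend <- .bn_update(backend, fw)
        B <- length(y)
        onehot <- cbind(y == 0, y == 1) * 1
        p_true <- rowSums(fw$probs * onehot)
        ep_loss <- ep_loss + sum(-log(pmax(p_true, 1e-12)))
        ep_correct <- ep_correct + sum((fw$probs[, 2] >= 0.5) == (y == 1))
        dlogits <- (fw$probs - onehot) / B
        grads <- .cnn_backward(backend, fw, dlogits)
        backend <- .adamw_step(backend, grads, lr)
      }
      backend$trained <- TRUE
      vp <- predict_proba(backend, val_images)
      val_loss <- mean(-log(pmax(ifelse(val_y == 1, vp, 1 - vp), 1e-12)))
      val_acc <- mean((vp >= 0.5) == (val_y == 1))
      tr_loss <- ep_loss / n_total
      tr_acc <- ep_correct / n_total
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = tr_loss, train_acc = tr_acc,
        val_loss = val_loss, val_acc = val_acc, acc_gap = tr_acc - val_acc,
        overfit = (tr_acc - val_acc) > 0.1)
      if (verbose)
        message(sprintf(
          "epoch %3d lr %.2e train %.3f/%.3f val %.3f/%.3f gap %+.3f",
          epoch, lr, tr_loss, tr_acc, val_loss, val_acc, tr_acc - val_acc))
      if (val_acc > best_acc + 1e-12) {
        best_acc <- val_acc; best_params <- backend$params; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= schedule$early_stop_patience) break
      }
    }
  })
  if (!is.null(best_params)) backend$params <- best_params
  list(backend = backend, history = do.call(rbind, history))
}

#' Predict slice probabilities for a dataset
#'
#' Applies evaluation-mode preprocessing (resize + normalize, no stochastic
#' augmentation) and returns one class-1 (AME) probability per slice, ordered
#' by the evaluation plan.
#'
#' @param backend A trained backend.
#' @param data A `slice_dataset`.
#' @param augment An [augment_params()].
#' @param plan Optional evaluation plan from [uniform_patient_batches()];
#'   default is manifest order.
#' @return data.frame with `patient_id`, `slice_index`, `label`, `prob`.
#' @export
predict_slices <- function(backend, data, augment = augment_params(),
                           plan = NULL) {
  man <- data$manifest
  if (is.null(plan)) {
    ord <- seq_len(nrow(man))
  } else {
    by_pat <- split(seq_len(nrow(man)), man$patient_id)
    ord <- mapply(function(p, k) by_pat[[p]][k],
                  plan$patient_id, plan$image_index)
  }
  imgs <- lapply(data$images[man$image_id[ord]], augment_slice,
                 params = augment, mode = "eval")
  probs <- predict_proba(backend, imgs)
  data.frame(patient_id = man$patient_id[ord],
             slice_index = man$slice_index[ord],
             label = man$label[ord], prob = probs,
             stringsAsFactors = FALSE)
}
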