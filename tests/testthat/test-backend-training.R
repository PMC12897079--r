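# The classifier backend contract: probability range, determinism, leakage
# guard, capacity on a separable toy task, and history bookkeeping.

toy_dataset <- function(ids, labels_by_id, seed = 3) {
  set.seed(seed)
  rows <- list(); images <- list(); n <- 0L
  for (i in seq_along(ids)) {
    for (s in 1:3) {
      n <- n + 1L
      y <- labels_by_id[i]
      m <- matrix(runif(64 * 64, 0, 100), 64, 64)
      if (y == 1) m[16:48, 16:48] <- m[16:48, 16:48] + 700
      images[[n]] <- m
      rows[[n]] <- data.frame(patient_id = ids[i], slice_index = s,
                              variant = "original", label = y, image_id = n,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(images = images, manifest = do.call(rbind, rows)),
            class = "slice_dataset")
}

quick_schedule <- function(max_epochs = 8)
  lr_schedule(warmup_epochs = 1, peak = 2e-3, phase2_start_epoch = max_epochs - 1,
              phase2_init = 1e-3, max_epochs = max_epochs,
              early_stop_patience = max_epochs)

test_that("a patient shared between train and validation is a hard error", {
  tr <- toy_dataset(c("A", "B", "C", "D"), c(0, 1, 0, 1))
  va <- toy_dataset(c("D", "E"), c(1, 0))
  expect_error(
    train_backend(cnn_backend(seed = 1), tr, va, schedule = quick_schedule()),
    "leakage")
})

test_that("the default CNN separates a trivial bright-square task", {
  tr <- toy_dataset(sprintf("T%02d", 1:12), rep(0:1, 6))
  va <- toy_dataset(sprintf("V%02d", 1:4), rep(0:1, 2), seed = 4)
  fit <- train_backend(cnn_backend(seed = 1), tr, va,
                       schedule = quick_schedule(8), seed = 5)
  expect_gte(max(fit$history$train_acc), 0.9)
  expect_gte(max(fit$history$val_acc), 0.9)
  # history bookkeeping
  expect_true(all(c("epoch", "lr", "train_loss", "train_acc", "val_loss",
                    "val_acc", "acc_gap", "overfit") %in%
                    names(fit$history)))
  sch <- quick_schedule(8)
  expect_equal(fit$history$lr,
               vapply(fit$history$epoch, lr_at_epoch, numeric(1), sch))
  expect_equal(fit$history$acc_gap,
               fit$history$train_acc - fit$history$val_acc)
})

test_that("training is reproducible for a fixed seed", {
  tr <- toy_dataset(sprintf("T%02d", 1:6), rep(0:1, 3))
  va <- toy_dataset(sprintf("V%02d", 1:2), 0:1, seed = 4)
  f1 <- train_backend(cnn_backend(seed = 2), tr, va,
                      schedule = quick_schedule(3), seed = 9)
  f2 <- train_backend(cnn_backend(seed = 2), tr, va,
                      schedule = quick_schedule(3), seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$backend$params, f2$backend$params)
})

test_that("predictions are probabilities, deterministic, and ordered by the plan", {
  tr <- toy_dataset(sprintf("T%02d", 1:6), rep(0:1, 3))
  va <- toy_dataset(sprintf("V%02d", 1:4), rep(0:1, 2), seed = 4)
  fit <- train_backend(cnn_backend(seed = 1), tr, va,
                       schedule = quick_schedule(3), seed = 5)
  pred <- predict_slices(fit$backend, va)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_identical(pred$prob, predict_slices(fit$backend, va)$prob)
  # an evaluation plan keeps each patient's slices contiguous
  plan <- uniform_patient_batches(table(va$manifest$patient_id), seed = 1)
  pred2 <- predict_slices(fit$backend, va, plan = plan)
  # batch composition may change BLAS summation order; values agree to
  # numerical precision
  expect_equal(sort(pred2$prob), sort(pred$prob), tolerance = 1e-9)
  expect_identical(pred2$patient_id, plan$patient_id)
  # duplicated input slice gives identical probabilities
  img <- augment_slice(va$images[[1]], augment_params(), "eval")
  p2 <- predict_proba(fit$backend, list(img, img))
  expect_equal(p2[1], p2[2])
})

test_that("an untrained backend refuses to predict", {
  b <- cnn_backend(seed = 1)
  expect_error(predict_proba(b, list(matrix(0, 64, 64))), "trained")
  expect_error(feature_grads(b, matrix(0, 64, 64)), "trained")
})
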