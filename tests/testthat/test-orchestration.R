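# NIfTI round-trips and the end-to-end comparative experiment contract.

test_that("volume/mask pairs round-trip through NIfTI with spacing", {
  cfg <- tiny_cohort_config(n_patients = 2, seed = 12)
  ch <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  pair <- read_volume_pair(file.path(dir, "P001_img.nii.gz"),
                           file.path(dir, "P001_mask.nii.gz"))
  expect_equal(pair$record$volume, unclass(ch$records[[1]]$volume),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(which(pair$mask$mask), which(ch$masks[[1]]$mask))
  expect_equal(unname(pair$record$spacing_mm), cfg$spacing_mm,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("misaligned or missing files raise informative errors", {
  cfg <- tiny_cohort_config(n_patients = 2, seed = 12)
  ch <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(ch, dir)
  expect_error(read_volume_pair(file.path(dir, "nope_img.nii.gz"),
                                file.path(dir, "P001_mask.nii.gz")),
               "not found")
  # a mask of the wrong shape
  bad <- RNifti::asNifti(array(0L, c(10, 10, 5)))
  badp <- file.path(dir, "bad_mask.nii.gz")
  RNifti::writeNifti(bad, badp)
  expect_error(read_volume_pair(file.path(dir, "P001_img.nii.gz"), badp),
               "mismatch")
  unlink(dir, recursive = TRUE)
})

test_that("the comparative experiment runs all variants over shared folds", {
  cfg <- tiny_cohort_config(n_patients = 6, seed = 31)
  ec <- experiment_config(
    cohort = cfg, variants = c("original", "bbox", "precise", "expanded"),
    k = 2, stride = 3,
    schedule = lr_schedule(warmup_epochs = 1, peak = 2e-3,
                           phase2_start_epoch = 2, phase2_init = 1e-3,
                           max_epochs = 2, early_stop_patience = 2),
    backend_factory = function() cnn_backend(seed = 4))
  rep <- suppressWarnings(run_experiment(ec))
  # 4 variants x 2 folds x 2 levels
  expect_named(rep$results, c("original", "bbox", "precise", "expanded"))
  for (v in names(rep$results))
    expect_length(rep$results[[v]]$folds, 2)
  expect_setequal(unique(rep$summary$level), c("slice", "patient"))

  # DeLong matrices: symmetric, unit diagonal, 6 unique off-diagonal pairs
  for (lev in c("slice", "patient")) {
    M <- rep$delong[[lev]]
    expect_identical(dim(M), c(4L, 4L))
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 1))
    expect_equal(sum(upper.tri(M)), 6)
  }
  # every patient appears in exactly one test fold
  expect_setequal(rep$partition$patient_id, sprintf("P%03d", 1:6))
  # provenance block carries the seeds needed to regenerate
  expect_true(all(c("seed_cohort", "seed_partition", "seed_training")
                  %in% names(rep$provenance)))
})

test_that("identical configurations give byte-identical reports", {
  cfg <- tiny_cohort_config(n_patients = 4, seed = 13)
  mk <- function() experiment_config(
    cohort = cfg, variants = "precise", k = 2, stride = 4,
    schedule = lr_schedule(warmup_epochs = 1, peak = 2e-3,
                           phase2_start_epoch = 2, phase2_init = 1e-3,
                           max_epochs = 2, early_stop_patience = 2),
    backend_factory = function() cnn_backend(seed = 4))
  r1 <- suppressWarnings(run_experiment(mk()))
  r2 <- suppressWarnings(run_experiment(mk()))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$results$precise$oof$prob, r2$results$precise$oof$prob)
  # written outputs round-trip
  dir <- tempfile("report")
  .write_report(r1, dir)
  expect_true(file.exists(file.path(dir, "metrics_summary.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  unlink(dir, recursive = TRUE)
})

test_that("cross-validation reports satisfy internal identities", {
  cfg <- tiny_cohort_config(n_patients = 4, seed = 17)
  ch <- generate_cohort(cfg)
  ds <- preprocess_cohort(ch, variants = "expanded", stride = 3)
  part <- partition_patients(ch$info$patient_id, ch$info$label, k = 2,
                             seed = 2)
  sch <- lr_schedule(warmup_epochs = 1, peak = 2e-3, phase2_start_epoch = 2,
                     phase2_init = 1e-3, max_epochs = 2,
                     early_stop_patience = 2)
  cv <- suppressWarnings(
    cross_validate(ds$expanded, part,
                   backend_factory = function() cnn_backend(seed = 4),
                   schedule = sch, seed = 3))
  for (f in cv$folds) {
    for (lev in c("slice", "patient")) {
      m <- f[[lev]]
      if (!is.na(m$precision) && !is.na(m$recall) &&
          (m$precision + m$recall) > 0)
        expect_equal(m$f1, 2 * m$precision * m$recall /
                       (m$precision + m$recall))
    }
  }
  # out-of-fold predictions cover every patient exactly once at patient level
  expect_setequal(cv$oof_patient$patient_id, ch$info$patient_id)
  # soft-vote identity: patient probability is the mean of its slice probs
  for (p in unique(cv$oof$patient_id)) {
    expect_equal(cv$oof_patient$prob[cv$oof_patient$patient_id == p],
                 mean(cv$oof$prob[cv$oof$patient_id == p]))
  }
})
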