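# Partitioning, confusion metrics, soft voting and the cohort statistics.

test_that("stratified patient folds are balanced and leak-free", {
  ids <- sprintf("P%03d", 1:128)
  labels <- rep(0:1, each = 64)
  p <- partition_patients(ids, labels, k = 5, seed = 1)
  sizes <- table(p$fold)
  expect_true(all(sizes %in% c(25, 26)))           # pigeonhole on 128/5
  expect_equal(sum(sizes), 128)                    # union covers the cohort
  expect_false(any(duplicated(p$patient_id)))      # one fold per patient
  # per-stratum sizes differ by at most one
  for (lab in 0:1) {
    s <- table(p$fold[p$label == lab])
    expect_lte(diff(range(s)), 1)
  }
  expect_identical(p, partition_patients(ids, labels, k = 5, seed = 1))
  expect_false(identical(p$fold,
                         partition_patients(ids, labels, k = 5, seed = 2)$fold))
})

test_that("k equal to the patient count gives singleton folds; k above it errors", {
  p <- partition_patients(letters[1:5], c(0, 1, 0, 1, 0), k = 5, seed = 3)
  expect_equal(sort(as.integer(table(p$fold))), rep(1L, 5))
  expect_error(partition_patients(letters[1:4], c(0, 1, 0, 1), k = 5),
               "exceeds")
})

test_that("classification metrics evaluate the defining formulas", {
  m <- classification_metrics(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$specificity, 0.8)

  perfect <- classification_metrics(confusion_matrix(c(1, 0, 1), c(1, 0, 1)))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f1")]) == 1))

  # everything predicted positive on a balanced set
  allpos <- classification_metrics(confusion_matrix(rep(0:1, 5), rep(1, 10)))
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$precision, 0.5)
  expect_equal(allpos$specificity, 0)
})

test_that("undefined ratios warn and yield NA, never silent zero", {
  expect_warning(m <- classification_metrics(list(tp = 0, fp = 0, fn = 2,
                                                  tn = 3)), "precision")
  expect_true(is.na(m$precision))
  expect_error(classification_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "degenerate")
})

test_that("soft voting averages slice probabilities with ties going to AME", {
  v <- patient_soft_vote(c(0.9, 0.8, 0.7))
  expect_equal(v$probability, 0.8)
  expect_equal(v$class, 1L)
  v2 <- patient_soft_vote(0.3)
  expect_equal(v2$class, 0L)
  v3 <- patient_soft_vote(c(0.4, 0.6))  # mean exactly at the threshold
  expect_equal(v3$probability, 0.5)
  expect_equal(v3$class, 1L)
  expect_error(patient_soft_vote(numeric(0)), "no slice")
})

test_that("chi-square reproduces the cohort-table p-values without continuity correction", {
  # sex, location, locularity, cortical integrity, impacted tooth (2x2)
  # and scanner (3x2), with the printed three-decimal p-values
  tabs <- list(
    sex        = list(m = matrix(c(32, 32, 30, 34), 2), p = 0.724),
    location   = list(m = matrix(c(4, 60, 9, 55), 2), p = 0.143),
    locularity = list(m = matrix(c(15, 49, 46, 18), 2), p = 0.000),
    cortical   = list(m = matrix(c(46, 18, 31, 33), 2), p = 0.007),
    impacted   = list(m = matrix(c(17, 47, 30, 34), 2), p = 0.017),
    scanner    = list(m = matrix(c(50, 8, 6, 49, 6, 9), 3), p = 0.639))
  for (nm in names(tabs)) {
    res <- pearson_chi_square(tabs[[nm]]$m)
    expect_equal(round(res$p, 3), tabs[[nm]]$p,
                 info = paste("table:", nm))
    expect_equal(res$df, (nrow(tabs[[nm]]$m) - 1))
  }
})

test_that("a table exactly at independence gives statistic 0 and p 1", {
  res <- pearson_chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2)), "expected")
})

test_that("Mann-Whitney U uses the exact small-sample distribution", {
  res <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(res$U), 0)
  # enumeration of all 20 rank arrangements: one-tail 1/20, two-sided 0.1
  expect_equal(res$p, 0.1)
  # symmetry under swapping the samples
  expect_equal(mann_whitney_u(c(10, 11, 12), c(1, 2, 3))$p, res$p)
  # identical samples: two-sided p = 1
  expect_equal(mann_whitney_u(1:10 + 0.5, 1:10 + 0.5)$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})
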