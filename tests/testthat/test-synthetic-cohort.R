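# The phantom generator: determinism, structural invariants, class counts,
# and convergence of feature frequencies to their configured probabilities.

test_that("cohort generation is deterministic and matches the class ratio", {
  cfg <- tiny_cohort_config(n_patients = 8, seed = 5)
  ch1 <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg)
  expect_identical(ch1$records[[3]]$volume, ch2$records[[3]]$volume)
  expect_identical(ch1$masks[[5]]$mask, ch2$masks[[5]]$mask)
  expect_equal(sum(ch1$info$label == 1), 4)
  expect_equal(sum(ch1$info$label == 0), 4)

  # 128 patients at ratio 0.5 -> 64/64 (labels only; tiny volumes)
  cfg128 <- cohort_config(n_patients = 128, volume_shape = c(24, 24, 20),
                          radius_range_mm = c(1.5, 2.5), seed = 9)
  ch128 <- generate_cohort(cfg128)
  expect_equal(as.vector(table(ch128$info$label)), c(64, 64))
})

test_that("every mask is nonempty, in bounds, aligned, and a single component", {
  cfg <- tiny_cohort_config(n_patients = 6, seed = 21)
  ch <- generate_cohort(cfg)
  for (i in seq_len(6)) {
    m <- ch$masks[[i]]$mask
    expect_identical(dim(m), dim(ch$records[[i]]$volume))
    expect_gt(sum(m), 0)
    # no foreground touching the outer voxel shell
    expect_equal(sum(m[c(1, dim(m)[1]), , ]) + sum(m[, c(1, dim(m)[2]), ]) +
                   sum(m[, , c(1, dim(m)[3])]), 0)
    expect_equal(mask_components(m), 1L)
  }
})

test_that("multilocular draws still produce one connected mask", {
  cfg <- tiny_cohort_config(
    n_patients = 2, seed = 3,
    class_feature_probs = list(
      ame = c(multilocular = 1, cortical_disruption = 0, septa_present = 1),
      okc = c(multilocular = 1, cortical_disruption = 1, septa_present = 1)))
  ch <- generate_cohort(cfg)
  for (i in 1:2) {
    expect_gte(ch$info$n_locules[i], 2)
    expect_equal(mask_components(ch$masks[[i]]$mask), 1L)
  }
})

test_that("the same (label, config, seed) triple reproduces voxel arrays", {
  cfg <- tiny_cohort_config()
  a <- generate_lesion_volume(1, cfg, seed = 77)
  b <- generate_lesion_volume(1, cfg, seed = 77)
  expect_identical(a$record$volume, b$record$volume)
  expect_identical(a$mask$mask, b$mask$mask)
  expect_false(identical(
    a$record$volume, generate_lesion_volume(1, cfg, seed = 78)$record$volume))
  expect_error(generate_lesion_volume(2, cfg, seed = 1), "label")
})

test_that("the noise-free, distractor-free background sits exactly at its level", {
  cfg <- tiny_cohort_config(n_patients = 2, noise_sd = 0,
                            distractor_count_range = c(0L, 0L))
  ch <- generate_cohort(cfg)
  for (i in 1:2) {
    vol <- ch$records[[i]]$volume
    m <- ch$masks[[i]]$mask
    # far from the lesion (outside a generous dilation) the volume is
    # exactly the background intensity
    far <- !m
    # exclude the interface band: anything not at background must be close
    # to the lesion
    off <- vol != cfg$background_intensity
    d <- dim(vol)
    idx <- which(off & far)
    if (length(idx) > 0) {
      pos <- arrayInd(idx, d)
      ctr <- colMeans(arrayInd(which(m), d))
      dist <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
      lesion_r <- max(sqrt(rowSums(sweep(arrayInd(which(m), d), 2, ctr)^2)))
      expect_lt(max(dist), lesion_r * 1.6 + 4)  # only the rim/spur band
    } else succeed()
  }
})

test_that("feature frequencies converge to the configured class probabilities", {
  cfg <- cohort_config(n_patients = 500, volume_shape = c(16, 16, 14),
                       radius_range_mm = c(1.2, 1.8), seed = 2026)
  ch <- generate_cohort(cfg)
  for (lab in 0:1) {
    p_target <- if (lab == 1) 0.766 else 0.281
    d <- ch$info[ch$info$label == lab, ]
    phat <- mean(d$multilocular)
    se <- sqrt(p_target * (1 - p_target) / nrow(d))
    expect_lt(abs(phat - p_target), 3 * se)
  }
})

test_that("background statistics carry no class signal", {
  cfg <- tiny_cohort_config(n_patients = 20, seed = 8)
  ch <- generate_cohort(cfg)
  # mean intensity outside a generous neighborhood of the lesion
  bg_stat <- vapply(seq_len(20), function(i) {
    vol <- ch$records[[i]]$volume; m <- ch$masks[[i]]$mask
    d <- dim(vol)
    ctr <- colMeans(arrayInd(which(m), d))
    pos <- arrayInd(seq_along(vol), d)
    lesion_r <- max(sqrt(rowSums(sweep(arrayInd(which(m), d), 2, ctr)^2)))
    far <- sqrt(rowSums(sweep(pos, 2, ctr)^2)) > 1.6 * lesion_r
    mean(vol[far])
  }, numeric(1))
  lab <- ch$info$label
  # permutation test on the class difference of background means
  obs <- abs(mean(bg_stat[lab == 1]) - mean(bg_stat[lab == 0]))
  set.seed(4)
  null <- replicate(999, {
    sh <- sample(lab)
    abs(mean(bg_stat[sh == 1]) - mean(bg_stat[sh == 0]))
  })
  expect_gt(mean(null >= obs), 0.01)  # nowhere near the permutation tail
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(class_ratio = 0), "class_ratio")
  expect_error(cohort_config(class_ratio = 1.2), "class_ratio")
  expect_error(cohort_config(spacing_mm = c(0.05, 0.3, 0.3)), "spacing")
  expect_error(cohort_config(radius_range_mm = c(5, 3)), "radius")
  expect_error(
    cohort_config(class_feature_probs = list(
      ame = c(multilocular = 1.4, cortical_disruption = 0, septa_present = 0),
      okc = c(multilocular = 0.2, cortical_disruption = 0.5,
              septa_present = 0.2))),
    "probabilities")
})
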