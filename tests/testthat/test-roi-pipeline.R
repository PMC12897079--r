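# Slice selection, square cropping, masking and dilation are checked against
# hand-computed geometry and brute-force oracles.

test_that("slice selection keeps areas strictly above the threshold and strides the retained list", {
  # per-slice areas 0,10,40,60,100,90,55,45,0 along the axial axis
  areas <- c(0, 10, 40, 60, 100, 90, 55, 45, 0)
  mask <- array(FALSE, c(12, 12, 9))
  for (k in seq_along(areas)) {
    m <- matrix(FALSE, 12, 12)
    if (areas[k] > 0) m[seq_len(areas[k])] <- TRUE
    mask[, , k] <- m
  }
  sel <- select_slices(mask, area_fraction = 0.5, stride = 1)
  # brute force: areas > 0.5 * 100 -> slices 4,5,6,7 (1-based)
  expect_identical(sel$slice_indices, which(areas > 0.5 * max(areas)))
  expect_identical(sel$slice_indices, c(4L, 5L, 6L, 7L))
  expect_equal(sel$max_area_vox, 100)

  # stride anchored at the first retained slice
  sel2 <- select_slices(mask, area_fraction = 0.5, stride = 2)
  expect_identical(sel2$slice_indices, c(4L, 6L))
})

test_that("stride over uniformly maximal slices picks every 5th starting at the first", {
  mask <- array(TRUE, c(4, 4, 12))
  sel <- select_slices(mask, area_fraction = 0.5, stride = 5)
  expect_identical(sel$slice_indices, c(1L, 6L, 11L))
})

test_that("slice selection requires a nonempty mask and is intensity-invariant", {
  expect_error(select_slices(array(FALSE, c(4, 4, 3))), "empty")
  cfg <- tiny_cohort_config(n_patients = 2)
  ch <- generate_cohort(cfg)
  sel <- select_slices(ch$masks[[1]])
  expect_gt(length(sel$slice_indices), 0)  # max-area slice always survives
  # selection depends only on the mask, not the volume
  expect_identical(sel$slice_indices,
                   select_slices(ch$masks[[1]], 0.5, 5)$slice_indices)
})

test_that("bbox square crop matches hand geometry with 20% expansion", {
  g <- geometry_slice()
  out <- bbox_square_roi(g$img, g$mask, expand = 0.20)
  # side = ceiling(1.2 * 20) = 24, centered at (50.5, 50.5):
  # rows 39-62, cols 39-62 (1-based)
  expect_identical(dim(out), c(24L, 24L))
  w <- attr(out, "window")
  expect_identical(unname(w), c(39L, 39L, 24L))
  expect_identical(out, structure(g$img[39:62, 39:62], window = w))
})

test_that("zero expansion on a square mask reproduces the bbox exactly", {
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(0, 64, 64); mask[11:30, 21:40] <- 1
  out <- bbox_square_roi(img, mask, expand = 0)
  expect_identical(dim(out), c(20L, 20L))
  expect_equal(unclass(out), img[11:30, 21:40], ignore_attr = TRUE)
})

test_that("crops extending past the image are zero-padded on all sides", {
  img <- matrix(1, 100, 100)
  mask <- matrix(1, 100, 100)
  out <- bbox_square_roi(img, mask, expand = 0.2)
  expect_identical(dim(out), c(120L, 120L))
  expect_true(all(out[1:10, ] == 0))
  expect_true(all(out[111:120, ] == 0))
  expect_true(all(out[, 1:10] == 0))
  expect_true(all(out[, 111:120] == 0))
  expect_true(all(out[11:110, 11:110] == 1))
})

test_that("mask_out is the elementwise product with the binarized mask", {
  img <- matrix(rnorm(25), 5, 5)
  mask <- matrix(rbinom(25, 1, 0.4), 5, 5)
  expect_equal(mask_out(img, mask), img * (mask > 0))
  expect_equal(mask_out(img, matrix(1, 5, 5)), img)
  expect_true(all(mask_out(img, matrix(0, 5, 5)) == 0))
  expect_error(mask_out(img, matrix(1, 4, 5)), "differ")
})

test_that("dilation uses the Euclidean digital disk of the rounded pixel radius", {
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  # margin 0.6 mm at 0.3 mm spacing -> radius 2 -> 13-pixel digital disk
  d <- dilate_mask(m, margin_mm = 0.6, spacing_mm = 0.3)
  expect_equal(sum(d), 13)
  # brute-force oracle over the 5x5 neighborhood with Euclidean radius 2
  oracle <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9)
    if ((i - 5)^2 + (j - 5)^2 <= 4) oracle[i, j] <- 1
  expect_equal(unclass(d), oracle, ignore_attr = TRUE)
})

test_that("dilation with zero margin is the identity and is always a superset", {
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  expect_equal(unclass(dilate_mask(m, 0, 0.3)), m, ignore_attr = TRUE)
  d <- dilate_mask(m, 1.2, 0.3)
  expect_true(all(d[m > 0] == 1))
  expect_error(dilate_mask(m, -1, 0.3), "margin")
})

test_that("make_input implements the four ROI variants", {
  cfg <- tiny_cohort_config(n_patients = 2, noise_sd = 0)
  ch <- generate_cohort(cfg)
  rec <- ch$records[[1]]; msk <- ch$masks[[1]]
  k <- select_slices(msk)$slice_indices[1]
  img <- rec$volume[, , k]; m2 <- msk$mask[, , k]
  sp <- rec$spacing_mm[1:2]

  expect_identical(make_input(img, m2, "original"), img)

  bb <- make_input(img, m2, "bbox")
  expect_identical(nrow(bb), ncol(bb))

  pr <- make_input(img, m2, "precise")
  # nonzero support equals mask within the crop
  w <- square_window(m2, 0.2)
  mcrop <- crop_window(m2, w)
  expect_true(all(pr[mcrop == 0] == 0))

  ex <- make_input(img, m2, "expanded", margin_mm = 3, spacing_mm = sp)
  # the expanded support strictly contains the precise support on this slice
  prn <- mask_out(crop_window(img, square_window(dilate_mask(m2, 3, sp), 0.2)),
                  crop_window(m2, square_window(dilate_mask(m2, 3, sp), 0.2)))
  expect_true(sum(ex != 0) > sum(prn != 0))
})

test_that("preprocess_cohort shares one slice selection across variants", {
  cfg <- tiny_cohort_config(n_patients = 3)
  ch <- generate_cohort(cfg)
  ds <- preprocess_cohort(ch, variants = c("precise", "expanded"), stride = 2)
  expect_identical(ds$precise$manifest$slice_index,
                   ds$expanded$manifest$slice_index)
  expect_identical(ds$precise$manifest$patient_id,
                   ds$expanded$manifest$patient_id)
  expect_s3_class(ds$precise, "slice_dataset")
})
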