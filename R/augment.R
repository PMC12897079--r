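#' Augmentation parameters
#'
#' The training pipeline resizes each slice to `target_size`, then applies a
#' random horizontal flip (probability `hflip_prob`), a random rotation within
#' `±rotation_deg` degrees and an affine transform with translation within
#' `±translate_frac` of the image size and isotropic scaling drawn from
#' `scale_range`, and finally normalizes intensities to `normalize_range`.
#' In evaluation mode only resizing and normalization are applied.
#'
#' @param target_size Output side length in pixels (default 64).
#' @param hflip_prob Horizontal flip probability (default 0.5).
#' @param rotation_deg Maximum absolute rotation in degrees (default 15).
#' @param translate_frac Maximum absolute translation fraction (default 0.05).
#' @param scale_range Scaling multipliers, low and high (default 0.95-1.05).
#' @param normalize_range Output intensity interval (default \[0, 1\]).
#' @param intensity_max Input intensity ceiling mapped to the top of
#'   `normalize_range` (default 1000, the generator's dynamic range).
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(target_size = 64L, hflip_prob = 0.5,
                           rotation_deg = 15, translate_frac = 0.05,
                           scale_range = c(0.95, 1.05),
                           normalize_range = c(0, 1),
                           intensity_max = 1000) {
  check_count(target_size, "target_size", lower = 8L)
  check_number(hflip_prob, "hflip_prob", lower = 0, upper = 1)
  check_number(rotation_deg, "rotation_deg", lower = 0)
  check_number(translate_frac, "translate_frac", lower = 0)
  if (length(scale_range) != 2L || scale_range[1] > scale_range[2] ||
      scale_range[1] <= 0)
    stopf("`scale_range` must be an increasing positive pair")
  structure(list(target_size = as.integer(target_size),
                 hflip_prob = hflip_prob, rotation_deg = rotation_deg,
                 translate_frac = translate_frac, scale_range = scale_range,
                 normalize_range = normalize_range,
                 intensity_max = intensity_max),
            class = "augment_params")
}

#' Draw one random augmentation transform
#'
#' Samples the stochastic part of the training augmentation (flip, rotation
#' angle, translation offsets, scale) from the configured ranges, using the
#' current RNG state. Exposed separately so the sampled distributions can be
#' checked independently of the image warp.
#'
#' @param params An [augment_params()] object.
#' @return List with `hflip`, `angle_deg`, `dr`, `dc` (pixels), `scale`.
#' @export
draw_augment_transform <- function(params) {
  list(hflip = stats::runif(1) < params$hflip_prob,
       angle_deg = stats::runif(1, -params$rotation_deg, params$rotation_deg),
       dr = stats::runif(1, -params$translate_frac, params$translate_frac) *
         params$target_size,
       dc = stats::runif(1, -params$translate_frac, params$translate_frac) *
         params$target_size,
       scale = stats::runif(1, params$scale_range[1], params$scale_range[2]))
}

.normalize_intensity <- function(img, params) {
  x <- img / params$intensity_max
  x[x < 0] <- 0; x[x > 1] <- 1
  params$normalize_range[1] + x * diff(params$normalize_range)
}

#' Augment one slice
#'
#' @param image 2D intensity matrix (raw generator units).
#' @param params An [augment_params()] object.
#' @param mode `"train"` (resize, random flip/rotate/affine, normalize) or
#'   `"eval"` (resize and normalize only; no stochastic operation).
#' @param seed Optional seed making the transform draw deterministic; the
#'   caller's RNG state is restored afterwards.
#' @return `target_size x target_size` matrix in `normalize_range`.
#' @export
augment_slice <- function(image, params, mode = c("train", "eval"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(image))) stopf("image contains non-finite values")
  n <- params$target_size
  if (mode == "eval") {
    out <- resize_bilinear(image, n, n)
  } else {
    # compose resize and affine into one sampling pass: inverse-map the
    # output grid through the affine in target space, then through the
    # resize scaling into source coordinates
    tr <- with_seed(seed, draw_augment_transform(params))
    ctr <- (n + 1) / 2
    out_r <- rep(seq_len(n), times = n) - ctr - tr$dr
    out_c <- rep(seq_len(n), each = n) - ctr - tr$dc
    th <- -tr$angle_deg * pi / 180
    rr <- (cos(th) * out_r - sin(th) * out_c) / tr$scale
    cs <- (sin(th) * out_r + cos(th) * out_c) / tr$scale
    if (tr$hflip) cs <- -cs
    src_r <- (rr + ctr - 0.5) * (nrow(image) / n) + 0.5
    src_c <- (cs + ctr - 0.5) * (ncol(image) / n) + 0.5
    out <- matrix(bilinear_sample(image, src_r, src_c), n, n)
  }
  .normalize_intensity(out, params)
}

#' Two-phase learning-rate schedule
#'
#' Linear warm-up to a peak rate, cosine decay toward `eta_min`, then a hard
#' reset to `phase2_init` at `phase2_start_epoch` followed by a second cosine
#' decay to `max_epochs`. The reset is the schedule's single upward
#' discontinuity; it restarts learning after the first plateau.
#'
#' @param warmup_epochs Warm-up length in epochs (default 5).
#' @param warmup_start,peak Learning rates at the start and end of warm-up.
#' @param eta_min Cosine floor.
#' @param phase2_start_epoch First epoch of phase 2 (default 51); must exceed
#'   `warmup_epochs`.
#' @param phase2_init Learning rate at the phase-2 reset.
#' @param max_epochs Last scheduled epoch.
#' @param early_stop_patience Epochs without validation improvement tolerated
#'   before stopping (default 10).
#' @return An object of class `lr_schedule`.
#' @export
lr_schedule <- function(warmup_epochs = 5L, warmup_start = 1e-4, peak = 1e-3,
                        eta_min = 1e-5, phase2_start_epoch = 51L,
                        phase2_init = 5e-4, max_epochs = 100L,
                        early_stop_patience = 10L) {
  warmup_epochs <- check_count(warmup_epochs, "warmup_epochs")
  phase2_start_epoch <- check_count(phase2_start_epoch, "phase2_start_epoch")
  max_epochs <- check_count(max_epochs, "max_epochs")
  if (phase2_start_epoch <= warmup_epochs)
    stopf("`phase2_start_epoch` must exceed `warmup_epochs`")
  if (max_epochs < phase2_start_epoch)
    stopf("`max_epochs` must be >= `phase2_start_epoch`")
  for (nm in c("warmup_start", "peak", "eta_min", "phase2_init"))
    check_number(get(nm), nm, lower = .Machine$double.xmin)
  structure(list(warmup_epochs = warmup_epochs, warmup_start = warmup_start,
                 peak = peak, eta_min = eta_min,
                 phase2_start_epoch = phase2_start_epoch,
                 phase2_init = phase2_init, max_epochs = max_epochs,
                 early_stop_patience = check_count(early_stop_patience,
                                                  "early_stop_patience")),
            class = "lr_schedule")
}

#' Learning rate at a given epoch
#'
#' @param epoch Epoch number, 1-based, at most `max_epochs`.
#' @param schedule An [lr_schedule()] object.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, schedule) {
  epoch <- check_count(epoch, "epoch")
  s <- schedule
  if (epoch > s$max_epochs)
    stopf("epoch %d exceeds max_epochs %d", epoch, s$max_epochs)
  cosine <- function(e, start_e, end_e, hi) {
    if (end_e <= start_e) return(hi)
    t <- (e - start_e) / (end_e - start_e)
    s$eta_min + (hi - s$eta_min) * (1 + cos(pi * t)) / 2
  }
  if (epoch <= s$warmup_epochs) {
    if (s$warmup_epochs == 1L) return(s$peak)
    return(s$warmup_start +
             (s$peak - s$warmup_start) * (epoch - 1) / (s$warmup_epochs - 1))
  }
  if (epoch < s$phase2_start_epoch)
    return(cosine(epoch, s$warmup_epochs, s$phase2_start_epoch - 1L, s$peak))
  cosine(epoch, s$phase2_start_epoch, s$max_epochs, s$phase2_init)
}
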