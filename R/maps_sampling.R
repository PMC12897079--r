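#' MAPS patient sampling weights
#'
#' Mode-Adaptive Patient-Centric Sampling computes per-patient training
#' weights from image counts: with `N_total` images over `P` patients, the
#' mean count is `N_bar = N_total / P`, the patient ratio is
#' `r_p = N_p / N_bar`, and the final weight is the capped ratio
#' `W_p = min(r_p, 2)`. The cap prevents patients contributing many slices
#' from dominating training, while the ratio keeps patients with few slices
#' from being oversampled.
#'
#' @param image_counts Named numeric vector (or named list) of per-patient
#'   image counts; all counts must be >= 1.
#' @return An object of class `maps_weights`: data.frame with columns
#'   `patient_id`, `n_images`, `r`, `w`, plus attributes `n_total`, `p`,
#'   `n_bar`.
#' @examples
#' maps_weights(c(A = 10, B = 20, C = 70))  # W = 0.3, 0.6, 2.0
#' @export
maps_weights <- function(image_counts) {
  counts <- unlist(image_counts)
  if (length(counts) < 1L) stopf("at least one patient is required")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stopf("`image_counts` must be named by patient id")
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stopf("all image counts must be integers >= 1")
  n_total <- sum(counts)
  p <- length(counts)
  n_bar <- n_total / p
  r <- counts / n_bar
  w <- pmin(r, 2.0)
  structure(data.frame(patient_id = names(counts),
                       n_images = as.integer(counts), r = unname(r),
                       w = unname(w), stringsAsFactors = FALSE),
            n_total = n_total, p = p, n_bar = n_bar,
            class = c("maps_weights", "data.frame"))
}

#' Draw a weighted training sample stream
#'
#' Training-mode MAPS sampling: patients are drawn with replacement with
#' probability proportional to their capped weight `W_p`, then one of the
#' drawn patient's images is picked uniformly (`level = "patient"`, the
#' default, patient-first hierarchical scheme). With `level = "image"` every
#' image is drawn directly with flat weight `W_p / N_p`; both schemes give
#' the same expected per-image draw probability `(W_p / sum(W)) / N_p`.
#'
#' @param weights A [maps_weights()] object.
#' @param n_draws Number of draws.
#' @param seed Integer seed; the draw sequence is deterministic per seed.
#' @param level `"patient"` (hierarchical) or `"image"` (flat per-image
#'   weighting).
#' @return data.frame with columns `patient_id` and `image_index` (index
#'   within the patient's own image list, 1-based).
#' @export
training_sampler <- function(weights, n_draws, seed = NULL,
                             level = c("patient", "image")) {
  if (!inherits(weights, "maps_weights"))
    stopf("`weights` must come from maps_weights()")
  level <- match.arg(level)
  n_draws <- check_count(n_draws, "n_draws")
  with_seed(seed, {
    if (level == "patient") {
      pi <- sample.int(nrow(weights), n_draws, replace = TRUE,
                       prob = weights$w)
      img <- floor(stats::runif(n_draws) * weights$n_images[pi]) + 1L
      data.frame(patient_id = weights$patient_id[pi],
                 image_index = as.integer(img), stringsAsFactors = FALSE)
    } else {
      per_img_w <- rep(weights$w / weights$n_images, weights$n_images)
      owner <- rep(seq_len(nrow(weights)), weights$n_images)
      within <- unlist(lapply(weights$n_images, seq_len))
      k <- sample.int(length(per_img_w), n_draws, replace = TRUE,
                      prob = per_img_w)
      data.frame(patient_id = weights$patient_id[owner[k]],
                 image_index = within[k], stringsAsFactors = FALSE)
    }
  })
}

#' Uniform patient-level evaluation plan
#'
#' Evaluation-mode MAPS sampling: every patient is visited exactly once per
#' pass (a permutation, no replacement) and, once a patient is sampled, all of
#' that patient's images are emitted contiguously in slice order. Each case
#' therefore contributes exactly once to patient-level metrics.
#'
#' @param image_counts Named vector of per-patient image counts.
#' @param seed Integer seed for the patient permutation.
#' @return data.frame with columns `patient_id` and `image_index`; one row per
#'   image, patients contiguous.
#' @export
uniform_patient_batches <- function(image_counts, seed = NULL) {
  counts <- unlist(image_counts)
  if (length(counts) < 1L) stopf("at least one patient is required")
  ord <- with_seed(seed, sample.int(length(counts)))
  data.frame(
    patient_id = rep(names(counts)[ord], counts[ord]),
    image_index = unlist(lapply(counts[ord], seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
}
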