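#' Grad-CAM map from feature activations and pooled gradients
#'
#' The attribution core: each channel's activation map is weighted by the
#' spatially pooled gradient of the target-class score, the weighted sum is
#' rectified, min-max normalized to \[0, 1\] (an identically zero map is left
#' at zero rather than divided by zero) and bilinearly upsampled to the
#' requested output size. The map is invariant to positive rescaling of the
#' gradients, since normalization absorbs scale.
#'
#' @param activations Array `[h, w, channels]` of feature-layer activations.
#' @param pooled_gradients One weight per channel.
#' @param out_size Output side length in pixels (no upsampling if equal to
#'   `h`).
#' @return Matrix `out_size x out_size` with values in \[0, 1\].
#' @export
grad_cam_map <- function(activations, pooled_gradients, out_size = NULL) {
  d <- dim(activations)
  if (length(d) != 3L) stopf("`activations` must be [h, w, channels]")
  if (length(pooled_gradients) != d[3])
    stopf("one pooled gradient per channel is required")
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + pooled_gradients[k] * activations[, , k]
  m[m < 0] <- 0
  if (!is.null(out_size) && out_size != d[1])
    m <- resize_bilinear(m, out_size, out_size)
  m[m < 0] <- 0
  if (max(m) > 0) m <- (m - min(m)) / (max(m) - min(m))
  m
}

#' Grad-CAM heatmap for one input image
#'
#' Computes the gradient-weighted class activation map of the backend's
#' designated final convolutional feature layer for the requested class, and
#' upsamples it to the input size.
#'
#' @param backend A trained backend exposing [feature_grads()].
#' @param image One prepared input matrix (model intensity range).
#' @param target_class Class whose score is attributed (default 1, AME).
#' @return An object of class `heatmap`: list with `values` (matrix in
#'   \[0, 1\], input size), `layer` and `target_class`.
#' @export
grad_cam <- function(backend, image, target_class = 1L) {
  fg <- feature_grads(backend, image, target_class = target_class)
  structure(list(values = grad_cam_map(fg$activations, fg$pooled_gradients,
                                       out_size = nrow(image)),
                 layer = "final convolutional block",
                 target_class = as.integer(target_class)),
            class = "heatmap")
}

#' Per-patient confidence curve with SD-based flagging
#'
#' The confidence curve is the trace of a patient's slice-level class-1
#' probabilities in sequential slice order; its spread measures diagnostic
#' consistency. The population standard deviation (the slice set is the whole
#' population for that patient) drives low-confidence flagging: a case is
#' flagged `"low"` when the SD exceeds `sd_threshold` or the mean lies within
#' `mean_band` of the 0.5 decision line, otherwise `"high"`.
#'
#' @param slice_probs The patient's slice probabilities in slice order.
#' @param sd_threshold Maximum SD of a high-confidence case (default 0.15).
#' @param mean_band Half-width of the indecision band around 0.5
#'   (default 0.1).
#' @param patient_id Optional identifier carried in the result.
#' @return An object of class `confidence_curve`: list with `probabilities`,
#'   `mean`, `sd` and `flag` (`"high"` or `"low"`).
#' @export
confidence_curve <- function(slice_probs, sd_threshold = 0.15,
                             mean_band = 0.1, patient_id = NA_character_) {
  if (length(slice_probs) < 1L) stopf("no slice probabilities supplied")
  if (any(slice_probs < 0 | slice_probs > 1))
    stopf("probabilities must lie in [0, 1]")
  m <- mean(slice_probs)
  s <- sqrt(mean((slice_probs - m)^2))  # population SD
  flag <- if (s > sd_threshold || abs(m - 0.5) <= mean_band) "low" else "high"
  structure(list(patient_id = patient_id, probabilities = slice_probs,
                 mean = m, sd = s, flag = flag),
            class = "confidence_curve")
}

#' Confidence summaries for every patient of a prediction table
#'
#' @param pred A slice prediction table as returned by [predict_slices()].
#' @param sd_threshold,mean_band Passed to [confidence_curve()].
#' @return data.frame with one row per patient: mean, sd, flag.
#' @export
confidence_summary <- function(pred, sd_threshold = 0.15, mean_band = 0.1) {
  do.call(rbind, lapply(split(pred, pred$patient_id), function(d) {
    d <- d[order(d$slice_index), ]
    cc <- confidence_curve(d$prob, sd_threshold, mean_band,
                           patient_id = d$patient_id[1])
    data.frame(patient_id = cc$patient_id, label = d$label[1],
               mean = cc$mean, sd = cc$sd, flag = cc$flag,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
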