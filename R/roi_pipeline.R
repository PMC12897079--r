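#' Select axial slices from a lesion mask
#'
#' Computes the lesion area of every axial slice (third array axis), keeps the
#' slices whose area is strictly greater than `area_fraction` times the
#' maximum per-slice area, and then takes every `stride`-th slice of the
#' retained, ordered list, anchored at its first element. The slice attaining
#' the maximum area always survives, so the result is never empty. The
#' selection depends on the mask only, never on intensities.
#'
#' @param mask A `LesionMask` (list with `patient_id` and a logical/binary 3D
#'   `mask` array) or a 3D array.
#' @param area_fraction Retention threshold in (0, 1\]; the comparison is
#'   strict (`>`). Default 0.5: slices with more than half of the maximum
#'   lesion area.
#' @param stride Sampling stride over the retained slices (default 5).
#' @return An object of class `slice_selection`: list with `patient_id`,
#'   `slice_indices` (1-based, strictly increasing), `areas` (per-slice lesion
#'   areas in voxels), `max_area_vox`, `area_fraction`, `stride`.
#' @export
select_slices <- function(mask, area_fraction = 0.5, stride = 5L) {
  pid <- NA_character_
  if (is.list(mask) && !is.null(mask$mask)) { pid <- mask$patient_id; mask <- mask$mask }
  if (length(dim(mask)) != 3L) stopf("`mask` must be a 3D array")
  check_number(area_fraction, "area_fraction", lower = 0, upper = 1)
  if (area_fraction == 0) stopf("`area_fraction` must be in (0, 1]")
  stride <- check_count(stride, "stride")
  areas <- apply(mask > 0, 3L, sum)
  if (max(areas) == 0) stopf("empty lesion mask: no foreground voxel")
  keep <- which(areas > area_fraction * max(areas))
  idx <- keep[seq(1L, length(keep), by = stride)]
  structure(list(patient_id = pid, slice_indices = idx, areas = areas,
                 max_area_vox = max(areas), area_fraction = area_fraction,
                 stride = stride),
            class = "slice_selection")
}

# Crop `mat` to the square window (r_start, c_start, side), zero-padding
# regions that fall outside the matrix.
crop_window <- function(mat, window) {
  r0 <- window[1]; c0 <- window[2]; side <- window[3]
  out <- matrix(0, side, side)
  rs <- max(1L, r0); re <- min(nrow(mat), r0 + side - 1L)
  cs <- max(1L, c0); ce <- min(ncol(mat), c0 + side - 1L)
  if (rs <= re && cs <= ce)
    out[(rs - r0 + 1L):(re - r0 + 1L), (cs - c0 + 1L):(ce - c0 + 1L)] <-
      mat[rs:re, cs:ce]
  out
}

# Square window covering the mask bounding box, grown by `expand` (total side
# growth) and centered on the bounding-box center.
square_window <- function(mask, expand) {
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stopf("empty mask: cannot locate a bounding box")
  r1 <- min(fg[, 1]); r2 <- max(fg[, 1])
  c1 <- min(fg[, 2]); c2 <- max(fg[, 2])
  side <- as.integer(ceiling((1 + expand) * max(r2 - r1 + 1L, c2 - c1 + 1L)))
  ctr_r <- (r1 + r2) / 2; ctr_c <- (c1 + c2) / 2
  c(r_start = as.integer(floor(ctr_r - side / 2 + 1)),
    c_start = as.integer(floor(ctr_c - side / 2 + 1)),
    side = side)
}

#' Mask-centered square bounding-box crop
#'
#' Step 1 of the ROI workflow: crop a square of side
#' `ceiling((1 + expand) * max(bbox_height, bbox_width))`, centered on the
#' center of the mask's bounding box. Regions outside the image are
#' zero-padded (not clamped), preserving the mask-centered property.
#'
#' @param image 2D intensity matrix.
#' @param mask Aligned 2D binary mask with at least one foreground pixel.
#' @param expand Total side growth fraction (default 0.20).
#' @return A `side x side` matrix; attribute `window` holds
#'   `(r_start, c_start, side)` of the crop in image coordinates.
#' @export
bbox_square_roi <- function(image, mask, expand = 0.20) {
  if (!all(dim(image) == dim(mask))) stopf("image and mask shapes differ")
  check_number(expand, "expand", lower = 0)
  w <- square_window(mask, expand)
  out <- crop_window(image, w)
  attr(out, "window") <- w
  out
}

#' Zero out intensities outside a mask
#'
#' Step 2 of the ROI workflow: the output equals the image where the mask is
#' foreground and 0 elsewhere (elementwise product with the binarized mask).
#'
#' @param image 2D intensity matrix.
#' @param mask Aligned 2D mask.
#' @return Matrix of the same shape.
#' @export
mask_out <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) stopf("image and mask shapes differ")
  image * (mask > 0)
}

# Euclidean disk structuring element of pixel radius r (the digital disk:
# all offsets with dx^2 + dy^2 <= r^2; r = 2 gives the 13-pixel disk).
disk_kernel <- function(r) {
  if (r == 0) return(matrix(1, 1, 1))
  d <- -r:r
  outer(d, d, function(i, j) as.numeric(i^2 + j^2 <= r^2))
}

#' Morphological dilation of a 2D mask by a physical margin
#'
#' Step 3 of the ROI workflow: binary dilation with a Euclidean disk
#' structuring element whose pixel radius is `round(margin_mm / spacing)`,
#' where `spacing` is the in-plane voxel size. The dilated mask is always a
#' superset of the input.
#'
#' @param mask 2D binary mask.
#' @param margin_mm Dilation margin in mm (>= 0; 0 returns the input
#'   binarized).
#' @param spacing_mm In-plane voxel size in mm (scalar, or a vector whose
#'   first two entries are averaged).
#' @return Binary (0/1) matrix of the same shape.
#' @export
dilate_mask <- function(mask, margin_mm, spacing_mm) {
  if (margin_mm < 0) stopf("`margin_mm` must be >= 0")
  sp <- if (length(spacing_mm) >= 2) mean(spacing_mm[1:2]) else spacing_mm[1]
  r <- round(margin_mm / sp)
  m <- (mask > 0) * 1
  if (r == 0) return(m)
  EBImage::dilate(m, disk_kernel(r))
}

.roi_variants <- c("original", "bbox", "precise", "expanded")

#' Build one classifier input from a slice and its mask
#'
#' Applies the ROI workflow for the requested variant:
#' \describe{
#'   \item{original}{the untouched slice;}
#'   \item{bbox}{mask-centered square crop only;}
#'   \item{precise}{square crop, then intensities outside the lesion mask
#'     zeroed;}
#'   \item{expanded}{the mask is first dilated by `margin_mm`; the square crop
#'     window is computed from the dilated mask's bounding box (so the margin
#'     is never clipped) and intensities outside the dilated mask are zeroed.}
#' }
#'
#' @param image_slice 2D intensity matrix (one axial slice).
#' @param mask_slice Aligned 2D lesion mask.
#' @param variant One of `"original"`, `"bbox"`, `"precise"`, `"expanded"`.
#' @param expand Square-crop side growth (default 0.20).
#' @param margin_mm Dilation margin for the expanded variant (default 3 mm).
#' @param spacing_mm In-plane voxel size in mm.
#' @return 2D matrix (square for bbox/precise/expanded).
#' @export
make_input <- function(image_slice, mask_slice, variant,
                       expand = 0.20, margin_mm = 3.0, spacing_mm = 0.3) {
  variant <- match.arg(variant, .roi_variants)
  if (!all(dim(image_slice) == dim(mask_slice)))
    stopf("slice and mask shapes differ")
  switch(variant,
    original = image_slice,
    bbox = bbox_square_roi(image_slice, mask_slice, expand),
    precise = {
      w <- square_window(mask_slice, expand)
      mask_out(crop_window(image_slice, w), crop_window(mask_slice, w))
    },
    expanded = {
      dm <- dilate_mask(mask_slice, margin_mm, spacing_mm)
      w <- square_window(dm, expand)
      mask_out(crop_window(image_slice, w), crop_window(dm, w))
    })
}

#' Preprocess a cohort into per-variant slice datasets
#'
#' Runs slice selection once per patient (the selection is shared by all
#' variants, so variants stay comparable) and builds the requested ROI inputs
#' for every selected slice.
#'
#' @param cohort A `lesion_cohort` (or list with `records` and `masks`).
#' @param variants Character vector of ROI variants to build.
#' @param area_fraction,stride Passed to [select_slices()].
#' @param expand,margin_mm Passed to [make_input()].
#' @return A named list (one element per variant) of `slice_dataset` objects:
#'   each has `images` (list of 2D matrices) and `manifest` (data.frame with
#'   patient_id, slice_index, variant, label, image_id).
#' @export
preprocess_cohort <- function(cohort, variants = .roi_variants,
                              area_fraction = 0.5, stride = 5L,
                              expand = 0.20, margin_mm = 3.0) {
  variants <- match.arg(variants, .roi_variants, several.ok = TRUE)
  sels <- lapply(cohort$masks, select_slices,
                 area_fraction = area_fraction, stride = stride)
  out <- list()
  for (v in variants) {
    images <- list(); rows <- list(); id <- 0L
    for (i in seq_along(cohort$records)) {
      rec <- cohort$records[[i]]; msk <- cohort$masks[[i]]
      for (k in sels[[i]]$slice_indices) {
        id <- id + 1L
        images[[id]] <- make_input(rec$volume[, , k], msk$mask[, , k], v,
                                   expand = expand, margin_mm = margin_mm,
                                   spacing_mm = rec$spacing_mm[1:2])
        rows[[id]] <- data.frame(patient_id = rec$patient_id,
                                 slice_index = k, variant = v,
                                 label = rec$label, image_id = id,
                                 stringsAsFactors = FALSE)
      }
    }
    out[[v]] <- structure(list(images = images,
                               manifest = do.call(rbind, rows)),
                          class = "slice_dataset")
  }
  out
}

#' @export
print.slice_dataset <- function(x, ...) {
  cat(sprintf("<slice_dataset> %d slices from %d patients (variant %s)\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              x$manifest$variant[1]))
  invisible(x)
}
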