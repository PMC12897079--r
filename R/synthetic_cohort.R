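#' Configuration for the synthetic phantom cohort
#'
#' Defines the statistical and geometric structure of a phantom cohort that
#' emulates a two-class jaw-lesion study: ameloblastoma (AME, label 1) versus
#' odontogenic keratocyst (OKC, label 0). The two classes differ in the
#' radiographic features that drive the classification task -- locularity,
#' internal septa, and cortical (rim) integrity -- while sharing the same
#' background distribution, so all class signal lives at the lesion and its
#' interface, never in the background.
#'
#' Intensities are arbitrary units in \[0, 1000\] (CT-like dynamic range,
#' mapped to \[0, 1\] at model input). The default per-class feature
#' probabilities follow the observed cohort frequencies: multilocular
#' 76.6\% (AME) vs 28.1\% (OKC), disrupted cortex 28.1\% vs 51.6\%; septa
#' frequencies mirror locularity since septa are its radiographic correlate
#' and are only rendered in multilocular lesions.
#'
#' @param n_patients Number of patients (>= 2).
#' @param class_ratio Fraction of class-1 (AME) patients, strictly in (0, 1).
#' @param volume_shape Integer vector of 3 voxel counts (x, y, z); the third
#'   axis is axial.
#' @param spacing_mm Voxel size per axis in mm, each in \[0.1, 1\].
#' @param class_feature_probs List with elements `ame` and `okc`, each a named
#'   vector of probabilities for `multilocular`, `cortical_disruption`,
#'   `septa_present`.
#' @param radius_range_mm Range of the lesion equivalent radius in mm.
#' @param distractor_count_range Integer range of distractor blobs per volume
#'   (spine/airway analogues placed outside the lesion); `c(0, 0)` disables
#'   them.
#' @param distractor_radius_mm Radius range of distractor blobs in mm.
#' @param background_intensity,lesion_intensity,septum_intensity,rim_intensity,distractor_intensity
#'   Intensity levels in arbitrary units in \[0, 1000\].
#' @param trace_smoothness Temperature of the smooth-min envelope used as
#'   the segmentation tracing, in normalized-radius units; larger values
#'   round the inter-locule creases more aggressively.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; cohort generation is a pure function of the
#'   configuration, seed included.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [generate_lesion_volume()]
#' @export
cohort_config <- function(n_patients = 128,
                          class_ratio = 0.5,
                          volume_shape = c(160L, 160L, 112L),
                          spacing_mm = c(0.3, 0.3, 0.3),
                          class_feature_probs = list(
                            ame = c(multilocular = 0.766,
                                    cortical_disruption = 0.281,
                                    septa_present = 0.766),
                            okc = c(multilocular = 0.281,
                                    cortical_disruption = 0.516,
                                    septa_present = 0.281)),
                          radius_range_mm = c(6, 15),
                          distractor_count_range = c(2L, 4L),
                          distractor_radius_mm = c(3, 6),
                          background_intensity = 400,
                          lesion_intensity = 120,
                          septum_intensity = 800,
                          rim_intensity = 850,
                          distractor_intensity = 700,
                          trace_smoothness = 0.22,
                          noise_sd = 20,
                          seed = 1L) {
  check_count(n_patients, "n_patients", lower = 2L)
  check_number(class_ratio, "class_ratio")
  if (class_ratio <= 0 || class_ratio >= 1)
    stopf("`class_ratio` must be strictly between 0 and 1")
  if (length(volume_shape) != 3L || any(volume_shape < 8) ||
      any(volume_shape != round(volume_shape)))
    stopf("`volume_shape` must be 3 integer voxel counts >= 8")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm < 0.1) || any(spacing_mm > 1.0))
    stopf("`spacing_mm` must be 3 values in [0.1, 1.0] mm")
  for (cls in c("ame", "okc")) {
    p <- class_feature_probs[[cls]]
    need <- c("multilocular", "cortical_disruption", "septa_present")
    if (is.null(p) || !all(need %in% names(p)))
      stopf("`class_feature_probs$%s` must name %s", cls,
            paste(need, collapse = ", "))
    if (any(p[need] < 0) || any(p[need] > 1))
      stopf("feature probabilities must lie in [0, 1]")
  }
  if (length(radius_range_mm) != 2L || radius_range_mm[1] <= 0 ||
      diff(radius_range_mm) < 0)
    stopf("`radius_range_mm` must be an increasing positive range")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(n_patients = as.integer(n_patients), class_ratio = class_ratio,
         volume_shape = as.integer(volume_shape), spacing_mm = spacing_mm,
         class_feature_probs = class_feature_probs,
         radius_range_mm = radius_range_mm,
         distractor_count_range = as.integer(distractor_count_range),
         distractor_radius_mm = distractor_radius_mm,
         background_intensity = background_intensity,
         lesion_intensity = lesion_intensity,
         septum_intensity = septum_intensity,
         rim_intensity = rim_intensity,
         distractor_intensity = distractor_intensity,
         trace_smoothness = trace_smoothness,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_config")
}

# Ellipsoid "normalized radius" field on a subgrid: f(x) = sqrt(sum(((x-c)/a)^2)).
# xs/ys/zs are voxel coordinate vectors; center/axes in voxel units.
.ellipsoid_f <- function(xs, ys, zs, center, axes) {
  dx2 <- ((xs - center[1]) / axes[1])^2
  dy2 <- ((ys - center[2]) / axes[2])^2
  dz2 <- ((zs - center[3]) / axes[3])^2
  sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
}

#' Generate one phantom volume with its lesion mask
#'
#' Builds a single patient's 3D intensity volume and aligned binary lesion
#' mask. The lesion is one ellipsoid (unilocular) or a chain of overlapping
#' ellipsoids (multilocular; the chained placement guarantees a single
#' connected component). Septa are rendered as thin high-intensity walls where
#' the boundary shells of two locules intersect; an intact cortex is rendered
#' as a thin corticated rim just outside the mask boundary (a disrupted cortex
#' leaves an angular gap in the rim). Distractor blobs of configurable
#' intensity are placed away from the lesion and are never inside the mask.
#' Additive Gaussian noise is applied last.
#'
#' @param label Class code: AME = 1, OKC = 0.
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same (label, config, seed) triple always
#'   yields identical voxel arrays.
#' @param patient_id Identifier stored in the returned record.
#' @return A list with elements `record` (patient_id, label, volume,
#'   spacing_mm), `mask` (patient_id, mask: logical 3D array), and `features`
#'   (the drawn radiographic feature flags).
#' @export
generate_lesion_volume <- function(label, config, seed,
                                   patient_id = "P000") {
  if (!label %in% c(0, 1)) stopf("`label` must be 0 (OKC) or 1 (AME)")
  shape <- config$volume_shape
  sp <- config$spacing_mm
  with_seed(seed, {
    probs <- config$class_feature_probs[[if (label == 1) "ame" else "okc"]]
    multiloc <- stats::runif(1) < probs[["multilocular"]]
    cort_disrupt <- stats::runif(1) < probs[["cortical_disruption"]]
    septa <- multiloc && stats::runif(1) < probs[["septa_present"]]

    r_eq <- stats::runif(1, config$radius_range_mm[1], config$radius_range_mm[2])
    center0 <- shape / 2 + stats::runif(3, -4, 4)

    n_loc <- if (multiloc) sample(2:4, 1) else 1L
    centers <- list(); axes_mm <- list()
    centers[[1]] <- center0
    axes_mm[[1]] <- r_eq * (if (multiloc) 0.72 else 1) * stats::runif(3, 0.8, 1.25)
    if (n_loc > 1) {
      for (i in 2:n_loc) {
        r_i <- r_eq * stats::runif(1, 0.65, 0.9) * 0.72
        ax <- r_i * stats::runif(3, 0.8, 1.25)
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        # center spacing below the sum of the minimal semi-axes -> overlap
        d_mm <- 0.92 * (min(axes_mm[[i - 1]]) + min(ax))
        centers[[i]] <- centers[[i - 1]] + d_mm * dir / sp
        axes_mm[[i]] <- ax
      }
    }
    axes_vox <- lapply(axes_mm, function(a) a / sp)

    # keep the whole lesion (plus rim band) inside the volume: shift, then
    # shrink if it still cannot fit
    ext_lo <- do.call(pmin, Map(function(c, a) c - 1.3 * a - 3, centers, axes_vox))
    ext_hi <- do.call(pmax, Map(function(c, a) c + 1.3 * a + 3, centers, axes_vox))
    shrink <- min(1, (shape - 3) / (ext_hi - ext_lo))
    if (shrink < 1) {
      axes_vox <- lapply(axes_vox, function(a) a * shrink)
      centers <- lapply(centers, function(c) center0 + (c - center0) * shrink)
      ext_lo <- do.call(pmin, Map(function(c, a) c - 1.3 * a - 3, centers, axes_vox))
      ext_hi <- do.call(pmax, Map(function(c, a) c + 1.3 * a + 3, centers, axes_vox))
    }
    shift <- pmax(0, 2 - ext_lo) - pmax(0, ext_hi - (shape - 1))
    centers <- lapply(centers, function(c) c + shift)

    lo <- pmax(1L, floor(ext_lo + shift))
    hi <- pmin(shape, ceiling(ext_hi + shift))
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]

    minf <- array(Inf, c(length(xs), length(ys), length(zs)))
    shell_count <- array(0L, dim(minf))
    near_count <- array(0L, dim(minf))
    soft_acc <- array(0, dim(minf))
    tau <- config$trace_smoothness
    for (i in seq_len(n_loc)) {
      f <- .ellipsoid_f(xs, ys, zs, centers[[i]], axes_vox[[i]])
      minf <- pmin(minf, f)
      shell_count <- shell_count + (f >= 0.88 & f <= 1.04)
      near_count <- near_count + (f <= 1.18)
      soft_acc <- soft_acc + exp(-f / tau)
    }
    cavity <- minf <= 1
    # the segmentation mask emulates an expert tracing: a smooth-min
    # envelope of the locule union that rounds the inter-locule crease
    # notches, the way a manual contour follows the overall boundary rather
    # than every bony crease (for a unilocular lesion it equals the cavity)
    softmin <- -tau * log(soft_acc)
    # bony septa are bone, not lesion tissue: the tracing covers the lucent
    # lesion within its smooth envelope and excludes the walls, which is
    # why a precise segmentation crop loses them while the expanded crop
    # (dilated tracing) recovers them
    wall <- if (septa) cavity & shell_count >= 2L else array(FALSE, dim(minf))
    mask_sub <- (softmin <= 1) & !wall
    # excluding walls can in degenerate orientations pinch the envelope;
    # the tracing is by definition one region, so keep the largest component
    keep <- cpp_largest_component(as.vector(mask_sub), length(xs),
                                  length(ys), length(zs))
    mask_sub <- array(keep, dim(mask_sub))

    vol <- array(config$background_intensity, shape)
    sub <- vol[xs, ys, zs]
    sub[cavity] <- config$lesion_intensity
    if (septa) sub[wall] <- config$septum_intensity
    # rim smoothness is a class feature expressed only at the interface:
    # unilocular lesions wear a smooth corticated ring of constant
    # thickness, multilocular lesions a scalloped ring whose thickness
    # oscillates with the in-plane azimuth
    ctr <- Reduce(`+`, centers) / n_loc
    if (multiloc) {
      k_sc <- sample(5:9, 1)
      ph <- stats::runif(1, 0, 2 * pi)
      az <- outer(xs - ctr[1], ys - ctr[2], function(a, b) atan2(b, a))
      w <- array(0.12 + 0.10 * sin(k_sc * az + ph),
                 c(length(xs), length(ys), length(zs)))
    } else {
      w <- 0.14
    }
    # the cortical shell and crease spurs follow the traced envelope from
    # the outside, so a precise segmentation crop always excludes them
    rim_band <- softmin > 1 & softmin <= 1 + w
    if (cort_disrupt) {
      # disrupted cortex: remove the rim inside a random cone
      g <- stats::rnorm(3); g <- g / sqrt(sum(g^2))
      ox <- (xs - ctr[1]); oy <- (ys - ctr[2]); oz <- (zs - ctr[3])
      nrm <- sqrt(outer(outer(ox^2, oy^2, "+"), oz^2, "+"))
      dotp <- (outer(outer(ox * g[1], oy * g[2], "+"), oz * g[3], "+")) /
        pmax(nrm, 1e-9)
      sub[rim_band & dotp < 0.3] <- config$rim_intensity
    } else {
      sub[rim_band] <- config$rim_intensity
    }
    if (septa) {
      # bony spurs at the inter-locule creases just outside the lucent
      # cavity: the scalloped-margin structure at the bone-lesion interface
      # (never part of the mask, so a precise segmentation crop excludes it)
      spur <- softmin > 1 & softmin <= 1.22 & near_count >= 2L
      sub[spur] <- config$septum_intensity
    }
    vol[xs, ys, zs] <- sub

    mask <- array(FALSE, shape)
    mask[xs, ys, zs] <- mask_sub

    # voxels the distractors must never touch (lesion plus a safety band)
    protect <- array(FALSE, shape)
    protect[xs, ys, zs] <- minf <= 1.4

    dcr <- config$distractor_count_range
    n_dist <- if (dcr[2] >= 1) sample(dcr[1]:dcr[2], 1) else 0L
    if (n_dist > 0) {
      target_vox <- 2 * r_eq / mean(sp)
      for (d in seq_len(n_dist)) {
        rd <- stats::runif(1, config$distractor_radius_mm[1],
                           config$distractor_radius_mm[2])
        ax <- rd * stats::runif(3, 0.8, 1.25) / sp
        ctr <- NULL
        dist_try <- target_vox
        for (att in 1:60) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          cand <- center0 + shift + dist_try * dir
          if (all(cand - ax >= 1) && all(cand + ax <= shape)) { ctr <- cand; break }
          if (att %% 10 == 0) dist_try <- dist_try * 0.85  # relax if infeasible
        }
        if (is.null(ctr)) next
        dlo <- pmax(1L, floor(ctr - ax)); dhi <- pmin(shape, ceiling(ctr + ax))
        dx <- dlo[1]:dhi[1]; dy <- dlo[2]:dhi[2]; dz <- dlo[3]:dhi[3]
        f <- .ellipsoid_f(dx, dy, dz, ctr, ax)
        dsub <- vol[dx, dy, dz]
        psub <- protect[dx, dy, dz]
        hit <- f <= 1 & !psub
        dsub[hit] <- config$distractor_intensity
        vol[dx, dy, dz] <- dsub
      }
    }

    if (config$noise_sd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd)
    vol[vol < 0] <- 0
    vol[vol > 1000] <- 1000

    list(record = list(patient_id = patient_id, label = as.integer(label),
                       volume = vol, spacing_mm = sp),
         mask = list(patient_id = patient_id, mask = mask),
         features = list(multilocular = multiloc,
                         cortical_disruption = cort_disrupt,
                         septa_present = septa,
                         n_locules = n_loc, r_eq_mm = r_eq))
  })
}

#' Generate a full phantom cohort
#'
#' Produces `n_patients` volume/mask pairs with class counts matching
#' `class_ratio` after rounding. Class-1 (AME) lesions are preferentially
#' multilocular with internal septa and an intact corticated rim; class-0
#' (OKC) lesions are preferentially unilocular with smooth margins and a
#' disrupted cortex, per the configured feature probabilities. Distractor
#' structures are generated by the same law for both classes, so the
#' background distribution carries no class signal.
#'
#' @param config A [cohort_config()].
#' @return An object of class `lesion_cohort`: a list with `records` (list of
#'   volume records), `masks` (list of aligned lesion masks), `info` (one row
#'   per patient: id, label, feature flags), and `config`.
#' @examples
#' cfg <- cohort_config(n_patients = 4, volume_shape = c(32, 32, 24),
#'                      radius_range_mm = c(2, 3), seed = 7)
#' ch <- generate_cohort(cfg)
#' table(ch$info$label)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("`config` must be created by cohort_config()")
  n <- config$n_patients
  n1 <- round(n * config$class_ratio)
  if (n1 < 1 || n1 > n - 1)
    stopf("class_ratio %.3f leaves an empty class for %d patients",
          config$class_ratio, n)
  labels <- c(rep(1L, n1), rep(0L, n - n1))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("P%03d", seq_len(n))
  records <- vector("list", n); masks <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_lesion_volume(labels[i], config, seeds[i], patient_id = ids[i])
    records[[i]] <- g$record
    masks[[i]] <- g$mask
    feats[[i]] <- g$features
  }
  info <- data.frame(
    patient_id = ids, label = labels,
    multilocular = vapply(feats, `[[`, logical(1), "multilocular"),
    cortical_disruption = vapply(feats, `[[`, logical(1), "cortical_disruption"),
    septa_present = vapply(feats, `[[`, logical(1), "septa_present"),
    n_locules = vapply(feats, `[[`, integer(1), "n_locules"),
    r_eq_mm = vapply(feats, `[[`, numeric(1), "r_eq_mm"),
    stringsAsFactors = FALSE)
  structure(list(records = records, masks = masks, info = info,
                 config = config),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("<lesion_cohort> %d patients (AME %d / OKC %d), volume %s @ %s mm\n",
              nrow(x$info), sum(x$info$label == 1), sum(x$info$label == 0),
              paste(x$config$volume_shape, collapse = "x"),
              paste(format(x$config$spacing_mm), collapse = "x")))
  invisible(x)
}

#' Write a cohort to NIfTI volume/mask pairs plus a cohort table
#'
#' Writes `<patient_id>_img.nii.gz` and `<patient_id>_mask.nii.gz` per patient
#' (the affine encodes voxel spacing) and `cohort.csv` with patient id, label
#' and feature flags.
#'
#' @param cohort A `lesion_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the written image files.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]; msk <- cohort$masks[[i]]
    ip <- file.path(dir, paste0(rec$patient_id, "_img.nii.gz"))
    mp <- file.path(dir, paste0(rec$patient_id, "_mask.nii.gz"))
    img <- RNifti::asNifti(rec$volume)
    RNifti::pixdim(img) <- rec$spacing_mm
    RNifti::writeNifti(img, ip)
    mimg <- RNifti::asNifti(array(as.integer(msk$mask), dim(msk$mask)))
    RNifti::pixdim(mimg) <- rec$spacing_mm
    RNifti::writeNifti(mimg, mp)
    paths <- c(paths, ip)
  }
  utils::write.csv(cohort$info, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(paths)
}
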