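#' Read an aligned NIfTI volume/mask pair
#'
#' Loads a volume and its lesion mask, reads the voxel spacing from the
#' affine and enforces voxel-for-voxel alignment.
#'
#' @param image_path,mask_path Paths to NIfTI files.
#' @return List with `record` (patient_id from the image filename, volume,
#'   spacing_mm; label is `NA` and must come from the cohort table) and
#'   `mask`.
#' @export
read_volume_pair <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!all(dim(img) == dim(msk)))
    stopf("image/mask shape mismatch: %s vs %s",
          paste(dim(img), collapse = "x"), paste(dim(msk), collapse = "x"))
  sp_i <- RNifti::pixdim(img); sp_m <- RNifti::pixdim(msk)
  if (max(abs(sp_i - sp_m)) > 1e-4)
    stopf("image/mask voxel spacing mismatch")
  pid <- sub("_(img|image)\\.nii(\\.gz)?$", "", basename(image_path))
  list(record = list(patient_id = pid, label = NA_integer_,
                     volume = unclass(img)[, , , drop = TRUE],
                     spacing_mm = sp_i[1:3]),
       mask = list(patient_id = pid,
                   mask = unclass(msk)[, , , drop = TRUE] > 0))
}

#' Configuration of the comparative ROI experiment
#'
#' Bundles everything needed to run the four-variant comparison end to end:
#' the phantom cohort (or a directory of NIfTI pairs), the preprocessing
#' parameters, the fold count, the per-concern seeds, and the backend,
#' schedule and augmentation settings. Seeds are split per concern (cohort /
#' partition / training) so stages can be re-run independently.
#'
#' @param cohort A [cohort_config()] (the cohort is generated) or a
#'   `lesion_cohort`.
#' @param variants ROI variants to compare (default all four).
#' @param area_fraction,stride,expand,margin_mm Preprocessing parameters
#'   (defaults 0.5, 5, 0.20, 3 mm).
#' @param k Number of cross-validation folds (default 5).
#' @param seed_partition,seed_training Stage seeds (the cohort seed lives in
#'   its config).
#' @param backend_factory Zero-argument function returning a fresh backend.
#' @param schedule,augment Training settings shared by all variants.
#' @param sampler_level,batch_size Passed to [train_backend()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              variants = c("original", "bbox", "precise",
                                           "expanded"),
                              area_fraction = 0.5, stride = 5L,
                              expand = 0.20, margin_mm = 3.0, k = 5L,
                              seed_partition = 1L, seed_training = 1L,
                              backend_factory = function() cnn_backend(),
                              schedule = lr_schedule(),
                              augment = augment_params(),
                              sampler_level = "patient", batch_size = 16L) {
  variants <- match.arg(variants, c("original", "bbox", "precise", "expanded"),
                        several.ok = TRUE)
  structure(list(cohort = cohort, variants = variants,
                 area_fraction = area_fraction, stride = stride,
                 expand = expand, margin_mm = margin_mm,
                 k = check_count(k, "k"),
                 seed_partition = seed_partition,
                 seed_training = seed_training,
                 backend_factory = backend_factory, schedule = schedule,
                 augment = augment, sampler_level = sampler_level,
                 batch_size = batch_size),
            class = "experiment_config")
}

#' Run the comparative ROI experiment
#'
#' Generates (or takes) the cohort, builds all ROI variants from the same
#' slice selection, draws one shared patient-level fold partition, trains and
#' evaluates every variant over the same folds with identical seeds and
#' augmentation, and assembles the report: per-variant per-fold metrics at
#' slice and patient level, pairwise DeLong p-value matrices at both levels
#' (on pooled out-of-fold predictions, which are paired across variants by
#' construction), per-patient confidence summaries, and a provenance block
#' from which the whole report can be regenerated.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: per-fold metrics and summaries are
#'   written as CSV and the aggregate report as JSON.
#' @param keep_backends Keep each fold's trained backend inside the
#'   per-variant results (for attribution analyses; default FALSE).
#' @param verbose Print stage progress.
#' @return An object of class `experiment_report`.
#' @export
run_experiment <- function(config, out_dir = NULL, keep_backends = FALSE,
                           verbose = FALSE) {
  if (!inherits(config, "experiment_config"))
    stopf("`config` must come from experiment_config()")
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- if (inherits(config$cohort, "lesion_cohort")) config$cohort
            else { say("generating cohort"); generate_cohort(config$cohort) }
  say("preprocessing %d variant(s)", length(config$variants))
  datasets <- preprocess_cohort(cohort, variants = config$variants,
                                area_fraction = config$area_fraction,
                                stride = config$stride, expand = config$expand,
                                margin_mm = config$margin_mm)
  partition <- partition_patients(cohort$info$patient_id, cohort$info$label,
                                  k = config$k, seed = config$seed_partition,
                                  stratify = TRUE)
  results <- list()
  for (v in config$variants) {
    say("cross-validating variant %s", v)
    results[[v]] <- cross_validate(
      datasets[[v]], partition, backend_factory = config$backend_factory,
      schedule = config$schedule, augment = config$augment,
      sampler_level = config$sampler_level, batch_size = config$batch_size,
      seed = config$seed_training, keep_backends = keep_backends,
      verbose = FALSE)
  }
  delong <- list(slice = .delong_matrix(results, "oof"),
                 patient = .delong_matrix(results, "oof_patient"))
  confidence <- lapply(results, function(r) confidence_summary(r$oof))
  summary_tab <- do.call(rbind, lapply(names(results), function(v)
    cbind(variant = v, results[[v]]$summary)))
  structure(list(results = results, summary = summary_tab, delong = delong,
                 confidence = confidence, partition = partition,
                 cohort = cohort, datasets = datasets,
                 provenance = list(
                   variants = config$variants, k = config$k,
                   area_fraction = config$area_fraction,
                   stride = config$stride, expand = config$expand,
                   margin_mm = config$margin_mm,
                   seed_cohort = if (inherits(config$cohort, "cohort_config"))
                     config$cohort$seed else cohort$config$seed,
                   seed_partition = config$seed_partition,
                   seed_training = config$seed_training,
                   package_version = as.character(utils::packageVersion("lesionroi")))),
            class = "experiment_report") -> report
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

# Pairwise DeLong p-value matrix over variants; predictions are aligned by
# (patient, slice) key so pairing is exact.
.delong_matrix <- function(results, field) {
  vs <- names(results)
  key <- function(d) if (is.null(d$slice_index)) d$patient_id
                     else paste(d$patient_id, d$slice_index)
  ref <- results[[1]][[field]]
  ref <- ref[order(key(ref)), ]
  p <- matrix(1, length(vs), length(vs), dimnames = list(vs, vs))
  for (i in seq_along(vs)) for (j in seq_along(vs)) {
    if (j <= i) next
    a <- results[[i]][[field]]; a <- a[order(key(a)), ]
    b <- results[[j]][[field]]; b <- b[order(key(b)), ]
    dt <- delong_test(a$label, a$prob, b$prob)
    p[i, j] <- p[j, i] <- dt$p
  }
  p
}

.write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$summary, file.path(out_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  for (v in names(report$results))
    utils::write.csv(report$results[[v]]$oof,
                     file.path(out_dir, paste0("oof_slices_", v, ".csv")),
                     row.names = FALSE)
  conf <- do.call(rbind, Map(cbind, variant = names(report$confidence),
                             report$confidence))
  utils::write.csv(conf, file.path(out_dir, "confidence_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, delong = report$delong,
         provenance = report$provenance),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> variants: %s; k = %d\n",
              paste(x$provenance$variants, collapse = ", "), x$provenance$k))
  s <- x$summary
  auc <- s[s$metric == "auc", ]
  for (lev in unique(auc$level)) {
    d <- auc[auc$level == lev, ]
    cat(sprintf("  %s-level AUC: %s\n", lev,
                paste(sprintf("%s %.3f±%.3f", d$variant, d$mean, d$sd),
                      collapse = "  ")))
  }
  invisible(x)
}
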