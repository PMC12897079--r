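# Small phantom configurations used across tests. Volumes are kept small so
# unit tests run in seconds; the statistical structure is the same as the
# default study-scale configuration.
tiny_cohort_config <- function(n_patients = 6, seed = 42, ...) {
  cohort_config(n_patients = n_patients,
                volume_shape = c(48L, 48L, 40L),
                radius_range_mm = c(3, 5),
                seed = seed, ...)
}

# 3D 6-connectivity components of a logical mask, via igraph (independent of
# any package internals).
mask_components <- function(mask) {
  vox <- which(mask)
  if (length(vox) == 0) return(0L)
  d <- dim(mask)
  idx <- arrayInd(vox, d)
  id <- seq_along(vox)
  key <- (idx[, 1] - 1) + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
  lookup <- new.env(hash = TRUE, size = length(vox))
  for (i in id) assign(as.character(key[i]), i, envir = lookup)
  edges <- integer(0)
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(idx, 2, off, "+")
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    nbkey <- (nb[, 1] - 1) + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    for (i in which(ok)) {
      j <- mget(as.character(nbkey[i]), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
  igraph::count_components(g)
}

# A deterministic slice + mask pair for ROI geometry tests.
geometry_slice <- function() {
  img <- matrix(seq_len(100 * 100) %% 97, 100, 100)
  mask <- matrix(0, 100, 100)
  mask[41:60, 46:55] <- 1   # bbox rows 41-60 (h 20), cols 46-55 (w 10)
  list(img = img, mask = mask)
}
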