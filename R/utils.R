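# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, lower)
  as.integer(x)
}

# Evaluate `expr` with the global RNG state set from `seed`, restoring the
# caller's RNG state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions.
# Positions are 1-based; anything outside [1, nrow] x [1, ncol] contributes 0.
bilinear_sample <- function(img, r, c) {
  cpp_bilinear(img, r, c)
}

# Bilinear resize to out_h x out_w with pixel-center alignment.
resize_bilinear <- function(img, out_h, out_w) {
  sr <- nrow(img) / out_h
  sc <- ncol(img) / out_w
  r <- (seq_len(out_h) - 0.5) * sr + 0.5
  c <- (seq_len(out_w) - 0.5) * sc + 0.5
  grid_r <- rep(r, times = out_w)
  grid_c <- rep(c, each = out_h)
  matrix(bilinear_sample(img, grid_r, grid_c), out_h, out_w)
}

# Inverse-mapped affine warp about the image center. Forward model:
# optional horizontal flip, then isotropic scale, then rotation by
# `angle_deg` (counter-clockwise in row/col space), then translation by
# (dr, dc) pixels. Outside pixels are filled with 0.
warp_affine <- function(img, angle_deg = 0, dr = 0, dc = 0, scale = 1,
                        hflip = FALSE) {
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  out_r <- rep(seq_len(H), times = W) - cr - dr
  out_c <- rep(seq_len(W), each = H) - cc - dc
  th <- -angle_deg * pi / 180  # inverse rotation
  rr <- (cos(th) * out_r - sin(th) * out_c) / scale
  cs <- (sin(th) * out_r + cos(th) * out_c) / scale
  if (hflip) cs <- -cs
  matrix(bilinear_sample(img, rr + cr, cs + cc), H, W)
}
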