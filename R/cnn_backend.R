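# Compact convolutional classifier backend.
#
# Feature maps are stored as 4D arrays [H, W, B, C] (batch before channels so
# im2col is a contiguous C++ gather feeding one BLAS matrix product per
# layer). Each of the four convolution blocks is 3x3 / stride 1 / zero-padded
# convolution -> batch normalization -> ReLU, the first three followed by 2x2
# max pooling. The fourth block is the attribution target ("final
# convolutional feature layer"); global average pooling and a small dense
# head with a dropout ladder produce the 2-class softmax.

#' Compact CNN classifier backend
#'
#' A 4-block convolutional network (conv-batchnorm-ReLU, max pooling after
#' the first three blocks) for 2-class slice classification at
#' `input_size x input_size` resolution, trained with AdamW under the
#' two-phase learning-rate schedule. The head applies a dropout ladder
#' between global average pooling and the softmax output. The fourth
#' convolution block is the designated feature layer for Grad-CAM. The
#' backend satisfies the classifier contract used throughout the package:
#' [train_backend()], [predict_proba()], [feature_grads()].
#'
#' The default dropout ladder (0.3/0.2/0.1) keeps the descending-ladder
#' regularization structure but scales the rates to this backend's narrow
#' head (32/16 units), where rates tuned for a 2048-feature transfer-learning
#' head would stop learning altogether.
#'
#' @param input_size Input side in pixels; must be divisible by 8
#'   (default 64).
#' @param channels Channel widths of the four convolution blocks.
#' @param hidden Widths of the two hidden dense layers.
#' @param dropout Dropout ladder probabilities (applied before each dense
#'   layer, top to bottom).
#' @param weight_decay Decoupled AdamW weight decay.
#' @param seed Seed for the He-normal weight initialization.
#' @return An object of class `cnn_backend` (untrained).
#' @export
cnn_backend <- function(input_size = 64L, channels = c(8L, 16L, 32L, 32L),
                        hidden = c(32L, 16L), dropout = c(0.3, 0.2, 0.1),
                        weight_decay = 1e-4, seed = 1L) {
  input_size <- check_count(input_size, "input_size", lower = 8L)
  if (input_size %% 8L != 0L) stopf("`input_size` must be divisible by 8")
  if (length(channels) != 4L) stopf("`channels` must have 4 entries")
  if (length(hidden) != 2L) stopf("`hidden` must have 2 entries")
  if (length(dropout) != 3L || any(dropout < 0) || any(dropout >= 1))
    stopf("`dropout` must be 3 probabilities in [0, 1)")
  obj <- list(input_size = input_size, channels = as.integer(channels),
              hidden = as.integer(hidden), dropout = dropout,
              weight_decay = weight_decay, seed = as.integer(seed),
              params = NULL, bn_mean = NULL, bn_var = NULL, opt = NULL,
              trained = FALSE)
  obj$params <- with_seed(seed, .cnn_init(obj))
  obj$bn_mean <- lapply(obj$channels, numeric)
  obj$bn_var <- lapply(obj$channels, function(C) rep(1, C))
  class(obj) <- "cnn_backend"
  obj
}

#' @export
print.cnn_backend <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cnn_backend> %dx%d input, conv %s, head %s, %s (%d parameters)\n",
              x$input_size, x$input_size, paste(x$channels, collapse = "-"),
              paste(x$hidden, collapse = "-"),
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Flat parameter list: cW{l} convolution kernels, g{l}/be{l} batch-norm
# scale/shift, dW{l}/db{l} dense weights/biases.
.cnn_init <- function(cfg) {
  p <- list()
  ch_in <- c(1L, cfg$channels[1:3])
  for (l in 1:4) {
    fan <- 9L * ch_in[l]
    p[[paste0("cW", l)]] <- .he_init(fan, cfg$channels[l], fan)
    p[[paste0("g", l)]] <- rep(1, cfg$channels[l])
    p[[paste0("be", l)]] <- numeric(cfg$channels[l])
  }
  d_in <- c(cfg$channels[4], cfg$hidden)
  d_out <- c(cfg$hidden, 2L)
  for (l in 1:3) {
    p[[paste0("dW", l)]] <- .he_init(d_in[l], d_out[l], d_in[l])
    p[[paste0("db", l)]] <- numeric(d_out[l])
  }
  p
}

# --- conv primitives on [H, W, B, C] arrays ------------------------------

.idx_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) { v <- builder(); .idx_cache[[key]] <- v }
  v
}

.im2col <- function(X) {
  d <- dim(X)
  cpp_im2col(X, d[1], d[2], d[3], d[4])
}

# Rearranged weights for the input-gradient pass: the gradient of a
# same-padded 3x3 correlation is the correlation of the output gradient with
# the 180-degree-rotated kernels, input/output channels swapped. Returns the
# (9*C_out x C_in) matrix consumed by .im2col(dZ) %*% Wt.
.flip_weights <- function(W, C_in) {
  C_out <- ncol(W)
  key <- paste0("flip_", C_in, "_", C_out)
  perm <- .cached(key, function() {
    o <- rep(1:9, each = C_out)      # row block of Wt
    co <- rep.int(1:C_out, 9L)       # row within block
    idx <- matrix(0L, 9L * C_out, C_in)
    for (ci in seq_len(C_in))
      idx[, ci] <- (10L - o - 1L) * C_in + ci + (co - 1L) * (9L * C_in)
    idx
  })
  Wt <- W[as.vector(perm)]  # flat gather (a matrix index would be positional)
  dim(Wt) <- dim(perm)
  Wt
}

.pool_fwd <- function(X) {
  d <- dim(X)
  p <- cpp_pool_fwd(X, d[1], d[2], d[3], d[4])
  dim(p$A) <- c(d[1] / 2L, d[2] / 2L, d[3], d[4])
  list(A = p$A, arg = p$arg, in_dim = d)
}

.pool_bwd <- function(pool, dY) {
  d <- pool$in_dim
  dX <- cpp_pool_bwd(dY, pool$arg, d[1], d[2], d[3], d[4])
  dim(dX) <- d
  dX
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# Forward pass over a batch. `Xb` is [H, W, B]; returns logits, probabilities
# and (when `keep = TRUE`) the caches needed for backprop / attribution plus
# the batch-norm statistics observed on this batch.
.cnn_forward <- function(backend, Xb, train = FALSE, keep = FALSE) {
  d <- dim(Xb); B <- d[3]
  p <- backend$params
  X <- Xb; dim(X) <- c(d[1], d[2], B, 1L)
  caches <- vector("list", 4L)
  bn_mu <- vector("list", 4L); bn_var <- vector("list", 4L)
  for (l in 1:4) {
    sd_in <- dim(X)
    M <- .im2col(X)
    Z <- M %*% p[[paste0("cW", l)]]
    if (train) {
      bn <- cpp_bn_relu_train(Z, p[[paste0("g", l)]], p[[paste0("be", l)]],
                              .bn_eps)
      bn_mu[[l]] <- bn$mu; bn_var[[l]] <- bn$var
    } else {
      bn <- list(A = cpp_bn_relu_eval(Z, p[[paste0("g", l)]],
                                      p[[paste0("be", l)]],
                                      backend$bn_mean[[l]],
                                      backend$bn_var[[l]], .bn_eps))
    }
    A <- bn$A
    dim(A) <- c(sd_in[1], sd_in[2], B, ncol(Z))
    pl <- if (l <= 3) .pool_fwd(A) else NULL
    if (keep) caches[[l]] <- list(M = M, bn = bn, pool = pl, a_dim = dim(A))
    X <- if (l <= 3) pl$A else A
  }
  feat <- X                                   # [s, s, B, C4]
  fd <- dim(feat)
  G <- matrix(colMeans(matrix(feat, fd[1] * fd[2], B * fd[4])), B, fd[4])
  drop_mask <- vector("list", 3L)
  H_ <- G
  dense_in <- vector("list", 3L); relu_mask <- vector("list", 2L)
  for (l in 1:3) {
    pr <- backend$dropout[l]
    if (train && pr > 0) {
      m <- matrix((stats::runif(length(H_)) >= pr) / (1 - pr),
                  nrow(H_), ncol(H_))
      H_ <- H_ * m
      drop_mask[[l]] <- m
    }
    dense_in[[l]] <- H_
    Z <- H_ %*% p[[paste0("dW", l)]] + rep(p[[paste0("db", l)]], each = B)
    if (l < 3) { relu_mask[[l]] <- Z > 0; H_ <- Z * (Z > 0) } else H_ <- Z
  }
  logits <- H_
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  out <- list(logits = logits, probs = probs, feat_dim = fd)
  if (train) { out$bn_mu <- bn_mu; out$bn_var <- bn_var }
  if (keep) {
    out$caches <- caches; out$G <- G; out$feat <- feat
    out$dense_in <- dense_in; out$relu_mask <- relu_mask
    out$drop_mask <- drop_mask
  }
  out
}

# Backward pass from dlogits (B x 2); returns gradients in the flat params
# layout.
.cnn_backward <- function(backend, fw, dlogits) {
  p <- backend$params
  gd <- vector("list", length(p)); names(gd) <- names(p)
  dH <- dlogits
  for (l in 3:1) {
    if (l < 3) dH <- dH * fw$relu_mask[[l]]
    inp <- fw$dense_in[[l]]
    gd[[paste0("dW", l)]] <- crossprod(inp, dH)
    gd[[paste0("db", l)]] <- colSums(dH)
    dH <- dH %*% t(p[[paste0("dW", l)]])
    if (!is.null(fw$drop_mask[[l]])) dH <- dH * fw$drop_mask[[l]]
  }
  fd <- fw$feat_dim
  # through global average pooling: gradient spread uniformly over positions;
  # [H, W, B, C] flattens position-first, so each (b, c) value repeats h*w times
  dX <- array(rep(as.vector(dH) / (fd[1] * fd[2]), each = fd[1] * fd[2]), fd)
  for (l in 4:1) {
    ca <- fw$caches[[l]]
    if (l <= 3) dX <- .pool_bwd(ca$pool, dX)
    dA <- dX
    dim(dA) <- c(length(dA) / ca$a_dim[4], ca$a_dim[4])
    bb <- cpp_bn_relu_bwd(dA, ca$bn$relu, ca$bn$zh, ca$bn$sd,
                          p[[paste0("g", l)]])
    gd[[paste0("g", l)]] <- bb$dgamma
    gd[[paste0("be", l)]] <- bb$dbeta
    dZ <- bb$dZ
    gd[[paste0("cW", l)]] <- crossprod(ca$M, dZ)
    if (l > 1) {
      din <- dim(fw$caches[[l - 1]]$pool$A)
      Wt <- .flip_weights(p[[paste0("cW", l)]], din[4])
      dZarr <- dZ
      dim(dZarr) <- c(din[1], din[2], din[3], ncol(dZ))
      dX <- .im2col(dZarr) %*% Wt
      dim(dX) <- din
    }
  }
  gd
}

# Update the batch-norm running statistics from one training batch.
.bn_update <- function(backend, fw) {
  for (l in 1:4) {
    backend$bn_mean[[l]] <- (1 - .bn_momentum) * backend$bn_mean[[l]] +
      .bn_momentum * fw$bn_mu[[l]]
    backend$bn_var[[l]] <- (1 - .bn_momentum) * backend$bn_var[[l]] +
      .bn_momentum * fw$bn_var[[l]]
  }
  backend
}

# One decoupled AdamW update, in place on the backend. Weight decay applies
# to weight matrices only, never to batch-norm scale/shift or biases.
.adamw_step <- function(backend, grads, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (is.null(backend$opt))
    backend$opt <- list(t = 0L,
                        m = lapply(backend$params, function(q) q * 0),
                        v = lapply(backend$params, function(q) q * 0))
  backend$opt$t <- backend$opt$t + 1L
  t <- backend$opt$t
  wd <- backend$weight_decay
  decay <- grepl("^(cW|dW)", names(backend$params))
  for (i in seq_along(backend$params)) {
    g <- grads[[names(backend$params)[i]]]
    m <- backend$opt$m[[i]] * beta1 + (1 - beta1) * g
    v <- backend$opt$v[[i]] * beta2 + (1 - beta2) * g^2
    backend$opt$m[[i]] <- m
    backend$opt$v[[i]] <- v
    q <- backend$params[[i]]
    if (decay[i]) q <- q - lr * wd * q
    backend$params[[i]] <- q - lr * (m / (1 - beta1^t)) /
      (sqrt(v / (1 - beta2^t)) + eps)
  }
  backend
}

.stack_batch <- function(images) {
  H <- nrow(images[[1]])
  array(unlist(images, use.names = FALSE), c(H, ncol(images[[1]]),
                                             length(images)))
}

#' Predict class-1 probabilities for prepared images
#'
#' @param backend A trained classifier backend.
#' @param images List of `input_size x input_size` matrices already in model
#'   intensity range (see [augment_slice()] eval mode), or a 3D array
#'   `[H, W, N]`.
#' @param ... Passed to methods.
#' @return Numeric vector of probabilities of class 1 (AME), in \[0, 1\].
#' @export
predict_proba <- function(backend, images, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.cnn_backend <- function(backend, images, ...) {
  if (!backend$trained) stopf("backend has not been trained")
  Xb <- if (is.list(images)) .stack_batch(images) else images
  n <- dim(Xb)[3]
  probs <- numeric(n)
  # chunked to bound the im2col working set
  for (s in seq(1L, n, 64L)) {
    e <- min(n, s + 63L)
    fw <- .cnn_forward(backend, Xb[, , s:e, drop = FALSE])
    probs[s:e] <- fw$probs[, 2]
  }
  probs
}

#' Feature-layer activations and pooled gradients for attribution
#'
#' Runs one image through the backend in evaluation mode and returns the
#' activations of the designated final convolutional feature layer together
#' with the gradient of the target-class logit with respect to those
#' activations, pooled spatially -- the two ingredients of Grad-CAM.
#'
#' @param backend A trained backend.
#' @param image One prepared `input_size x input_size` matrix.
#' @param target_class Class whose logit is differentiated (0 or 1).
#' @param ... Passed to methods.
#' @return List with `activations` (array `[h, w, channels]`) and
#'   `pooled_gradients` (one weight per channel).
#' @export
feature_grads <- function(backend, image, target_class = 1L, ...)
  UseMethod("feature_grads")

#' @rdname feature_grads
#' @export
feature_grads.cnn_backend <- function(backend, image, target_class = 1L, ...) {
  if (!backend$trained) stopf("backend has not been trained")
  if (!target_class %in% c(0, 1)) stopf("`target_class` must be 0 or 1")
  Xb <- array(image, c(dim(image), 1L))
  fw <- .cnn_forward(backend, Xb, train = FALSE, keep = TRUE)
  # head backward for the target logit only (eval mode: no dropout)
  dH <- matrix(0, 1, 2); dH[1, target_class + 1L] <- 1
  for (l in 3:1) {
    if (l < 3) dH <- dH * fw$relu_mask[[l]]
    dH <- dH %*% t(backend$params[[paste0("dW", l)]])
  }
  fd <- fw$feat_dim
  A <- array(fw$feat, c(fd[1], fd[2], fd[4]))
  list(activations = A, pooled_gradients = as.numeric(dH) / (fd[1] * fd[2]))
}
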