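# Layer primitives operating on minibatches. A batch is a list of
# feature-map arrays [X, Y, Z, C]; the 2-D network is the Z = 1 case.
# Forward functions return list(out = <batch>, cache = ...); backward
# functions take the upstream gradients and return input gradients plus
# parameter gradients. All heavy lifting is in the C++ kernels.

conv_fwd_batch <- function(xs, w, b) {
  lapply(xs, conv3d_valid_forward, w = w, b = b)
}

conv_bwd_batch <- function(xs, w, douts) {
  dw <- NULL; db <- NULL
  dxs <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    g <- conv3d_valid_backward(xs[[i]], w, douts[[i]])
    dxs[[i]] <- g$dx
    if (is.null(dw)) { dw <- g$dw; db <- g$db }
    else { dw <- dw + g$dw; db <- db + g$db }
  }
  list(dx = dxs, dw = dw, db = db)
}

relu_fwd_batch <- function(xs) {
  relu_fwd_cpp(xs)
}

relu_bwd_batch <- function(outs, douts) {
  relu_bwd_cpp(outs, douts)
}

# Batch normalisation per channel over batch and spatial dimensions.
# Training uses minibatch statistics and updates running estimates;
# inference uses the running estimates (an affine map).
bn_fwd_batch <- function(xs, prm, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    st <- bn_stats_cpp(xs)
    n <- st$n
    mu <- st$sum / n
    varv <- pmax(st$sum2 / n - mu^2, 0)
    prm$running_mean <- (1 - momentum) * prm$running_mean + momentum * mu
    prm$running_var <- (1 - momentum) * prm$running_var + momentum * varv
  } else {
    n <- 1
    mu <- prm$running_mean
    varv <- prm$running_var
  }
  inv_sd <- 1 / sqrt(varv + eps)
  ap <- bn_apply_cpp(xs, mu, inv_sd, prm$gamma, prm$beta)
  list(out = ap$out, prm = prm,
       cache = list(xhat = ap$xhat, inv_sd = inv_sd, n = n, train = train))
}

bn_bwd_batch <- function(prm, cache, douts) {
  bn_bwd_cpp(cache$xhat, douts, prm$gamma, cache$inv_sd, cache$n,
             cache$train)
}

pool_fwd_batch <- function(xs, p) {
  res <- lapply(xs, maxpool3d_forward, p = as.integer(p))
  list(out = lapply(res, `[[`, "y"),
       cache = list(argmax = lapply(res, `[[`, "argmax"),
                    xdim = dim(xs[[1]])))
}

pool_bwd_batch <- function(cache, douts) {
  Map(function(d, am) maxpool3d_backward(d, am, as.integer(cache$xdim)),
      douts, cache$argmax)
}

up_fwd_batch <- function(xs, p) {
  lapply(xs, upsample3d_forward, p = as.integer(p))
}

up_bwd_batch <- function(xdim, p, douts) {
  lapply(douts, upsample3d_backward, p = as.integer(p),
         xdim = as.integer(xdim))
}

# Centre-crop spatial extents of a feature map to `target` (per-axis).
crop_center <- function(x, target) {
  d <- dim(x)[1:3]
  off <- (d - target) %/% 2L
  x[off[1] + seq_len(target[1]), off[2] + seq_len(target[2]),
    off[3] + seq_len(target[3]), , drop = FALSE]
}

# Adjoint of crop_center: place gradient back into a zero array of the
# uncropped extent.
uncrop_center <- function(dx, full_dim) {
  out <- array(0, dim = full_dim)
  d <- dim(dx)[1:3]
  off <- (full_dim[1:3] - d) %/% 2L
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
      off[3] + seq_len(d[3]), ] <- dx
  out
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(array(x[, , , seq_len(c1), drop = FALSE], dim = c(d[1:3], c1)),
       array(x[, , , c1 + seq_len(d[4] - c1), drop = FALSE],
             dim = c(d[1:3], d[4] - c1)))
}

# Channel softmax for the two-channel output.
softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), dim = d)
}
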