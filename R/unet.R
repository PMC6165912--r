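#' Construct a trainable valid-convolution U-Net
#'
#' Builds the weight set for the network described by an [arch_spec()]:
#' per resolution level a block of unpadded convolutions (each followed
#' by batch normalisation and a ReLU), max-pooling between encoder
#' levels, nearest-neighbour upsampling plus a centre-cropped skip
#' concatenation between decoder levels, and a final 1-voxel convolution
#' onto two channels with a softmax. Convolution weights use He
#' initialisation; initialisation is a pure function of `seed` (the
#' caller's RNG state is preserved).
#'
#' @param spec an [arch_spec()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `unet` holding the spec, parameters and
#'   batch-normalisation running statistics.
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  k <- kernel_per_axis(spec)
  L <- spec$levels
  W <- spec$base_channels
  chan <- W * 2L^(seq_len(L) - 1L)

  params <- list()
  buffers <- list()
  add_conv <- function(name, cin, cout, kext) {
    fan_in <- prod(kext) * cin
    params[[paste0(name, "_w")]] <<-
      array(stats::rnorm(prod(kext) * cin * cout, sd = sqrt(2 / fan_in)),
            dim = c(kext, cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
    if (spec$batch_norm) {
      params[[paste0(name, "_gamma")]] <<- rep(1, cout)
      params[[paste0(name, "_beta")]] <<- numeric(cout)
      buffers[[paste0(name, "_running_mean")]] <<- numeric(cout)
      buffers[[paste0(name, "_running_var")]] <<- rep(1, cout)
    }
  }
  for (l in seq_len(L)) {
    cin <- if (l == 1L) 1L else chan[l - 1L]
    for (i in seq_len(spec$convs_per_block)) {
      add_conv(sprintf("enc%d_c%d", l, i), cin, chan[l], k)
      cin <- chan[l]
    }
  }
  if (L > 1L) for (l in seq_len(L - 1L)) {
    cin <- chan[l] + chan[l + 1L]
    for (i in seq_len(spec$convs_per_block)) {
      add_conv(sprintf("dec%d_c%d", l, i), cin, chan[l], k)
      cin <- chan[l]
    }
  }
  add_conv("final", chan[1L], spec$output_channels, rep(1L, 3L))
  # final layer: plain conv + softmax, no BN/ReLU
  params$final_gamma <- NULL; params$final_beta <- NULL
  buffers$final_running_mean <- NULL; buffers$final_running_var <- NULL

  structure(list(spec = spec, params = params, buffers = buffers,
                 seed = as.integer(seed)),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet> %d-D, %d levels, base width %d, %d parameters\n",
              x$spec$dimensionality, x$spec$levels, x$spec$base_channels,
              as.integer(npar)))
  invisible(x)
}

# Per-axis kernel and pool factors in internal (x,y,z) array layout;
# the 2-D network is flat along z.
kernel_per_axis <- function(spec) {
  if (spec$dimensionality == 3L) rep(spec$kernel_extent, 3L)
  else c(spec$kernel_extent, spec$kernel_extent, 1L)
}

pool_per_axis <- function(spec) {
  if (spec$dimensionality == 3L) rep(spec$pool_extent, 3L)
  else c(spec$pool_extent, spec$pool_extent, 1L)
}

# Forward pass over a minibatch (list of [X,Y,Z,1] arrays, identical
# extents). Returns probs and, when keep_cache = TRUE, everything the
# backward pass needs. Training mode updates BN running statistics
# (returned via $model).
unet_forward <- function(model, xs, train = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  p <- pool_per_axis(spec)
  L <- spec$levels
  ext <- dim(xs[[1]])[1:3]
  # fail early with the tracer's diagnosis
  for (ax in seq_len(spec$dimensionality)) trace_extent_1d(spec, ext[ax])

  h <- xs
  encC <- vector("list", L); poolC <- vector("list", max(L - 1L, 0L))
  skips <- vector("list", max(L - 1L, 0L))
  for (l in seq_len(L)) {
    cb <- conv_block_fwd(model, h, sprintf("enc%d", l), train, keep_cache)
    model <- cb$model; h <- cb$out; encC[[l]] <- cb$cache
    if (l < L) {
      skips[[l]] <- h
      pc <- pool_fwd_batch(h, p)
      poolC[[l]] <- pc$cache
      h <- pc$out
    }
  }
  decC <- vector("list", max(L - 1L, 0L))
  upDims <- vector("list", max(L - 1L, 0L))
  concatInfo <- vector("list", max(L - 1L, 0L))
  if (L > 1L) for (l in rev(seq_len(L - 1L))) {
    upDims[[l]] <- dim(h[[1]])
    h <- up_fwd_batch(h, p)
    target <- dim(h[[1]])[1:3]
    skipFull <- dim(skips[[l]][[1]])
    s <- lapply(skips[[l]], crop_center, target = target)
    concatInfo[[l]] <- list(c1 = skipFull[4], skipFull = skipFull)
    h <- Map(concat_channels, s, h)
    cb <- conv_block_fwd(model, h, sprintf("dec%d", l), train, keep_cache)
    model <- cb$model; h <- cb$out; decC[[l]] <- cb$cache
  }
  finalX <- h
  logits <- conv_fwd_batch(h, model$params$final_w, model$params$final_b)
  probs <- lapply(logits, softmax_channels)
  out <- list(probs = probs, model = model)
  if (keep_cache)
    out$cache <- list(encC = encC, poolC = poolC, decC = decC,
                      upDims = upDims, concatInfo = concatInfo,
                      finalX = finalX, probs = probs)
  out
}

conv_block_fwd <- function(model, xs, prefix, train, keep_cache) {
  spec <- model$spec
  cache <- list()
  for (i in seq_len(spec$convs_per_block)) {
    nm <- sprintf("%s_c%d", prefix, i)
    cc <- list(x = if (keep_cache) xs else NULL)
    h <- conv_fwd_batch(xs, model$params[[paste0(nm, "_w")]],
                        model$params[[paste0(nm, "_b")]])
    if (spec$batch_norm) {
      prm <- list(gamma = model$params[[paste0(nm, "_gamma")]],
                  beta = model$params[[paste0(nm, "_beta")]],
                  running_mean = model$buffers[[paste0(nm, "_running_mean")]],
                  running_var = model$buffers[[paste0(nm, "_running_var")]])
      bf <- bn_fwd_batch(h, prm, train)
      model$buffers[[paste0(nm, "_running_mean")]] <- bf$prm$running_mean
      model$buffers[[paste0(nm, "_running_var")]] <- bf$prm$running_var
      h <- bf$out
      cc$bn <- if (keep_cache) bf$cache else NULL
    }
    h <- relu_fwd_batch(h)
    cc$relu_out <- if (keep_cache) h else NULL
    cache[[i]] <- cc
    xs <- h
  }
  list(model = model, out = xs, cache = cache)
}

conv_block_bwd <- function(model, cache, prefix, douts, G) {
  spec <- model$spec
  for (i in rev(seq_len(spec$convs_per_block))) {
    nm <- sprintf("%s_c%d", prefix, i)
    cc <- cache[[i]]
    douts <- relu_bwd_batch(cc$relu_out, douts)
    if (spec$batch_norm) {
      prm <- list(gamma = model$params[[paste0(nm, "_gamma")]],
                  beta = model$params[[paste0(nm, "_beta")]])
      bb <- bn_bwd_batch(prm, cc$bn, douts)
      G[[paste0(nm, "_gamma")]] <- bb$dgamma
      G[[paste0(nm, "_beta")]] <- bb$dbeta
      douts <- bb$dx
    }
    cb <- conv_bwd_batch(cc$x, model$params[[paste0(nm, "_w")]], douts)
    G[[paste0(nm, "_w")]] <- cb$dw
    G[[paste0(nm, "_b")]] <- cb$db
    douts <- cb$dx
  }
  douts
}

# Backward pass: dprobs_fg is a batch of gradients of the loss w.r.t.
# the foreground probability map. Returns a named list of parameter
# gradients matching model$params.
unet_backward <- function(model, cache, dprobs_fg) {
  spec <- model$spec
  p <- pool_per_axis(spec)
  L <- spec$levels
  G <- new.env(parent = emptyenv())

  # through softmax: p1 = fg prob, dL/dz1 = dL/dp1 * p1 * (1 - p1)
  dlogits <- Map(function(pr, dp) {
    d <- dim(pr)
    p1 <- pr[, , , 2, drop = FALSE]
    g <- dp * p1 * (1 - p1)
    array(c(-g, g), dim = d)
  }, cache$probs, dprobs_fg)

  cb <- conv_bwd_batch(cache$finalX, model$params$final_w, dlogits)
  G[["final_w"]] <- cb$dw
  G[["final_b"]] <- cb$db
  d <- cb$dx

  dskip <- vector("list", max(L - 1L, 0L))
  if (L > 1L) for (l in seq_len(L - 1L)) {
    d <- conv_block_bwd(model, cache$decC[[l]], sprintf("dec%d", l), d, G)
    ci <- cache$concatInfo[[l]]
    parts <- lapply(d, split_channels, c1 = ci$c1)
    dskip[[l]] <- lapply(parts, function(pp)
      uncrop_center(pp[[1]], ci$skipFull))
    d <- up_bwd_batch(cache$upDims[[l]], p, lapply(parts, `[[`, 2))
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      d <- pool_bwd_batch(cache$poolC[[l]], d)
      d <- Map(`+`, d, dskip[[l]])
    }
    d <- conv_block_bwd(model, cache$encC[[l]], sprintf("enc%d", l), d, G)
  }
  as.list(G)
}

#' Foreground probability for a single input patch
#'
#' Runs one inference-mode forward pass on an already-normalised input
#' patch and returns the foreground-probability array of the classified
#' valid centre (input extent minus the valid reduction per axis). For
#' full volumes in Hounsfield units use [predict_3d_tiled()] /
#' [predict_2d()] instead.
#'
#' @param model a `unet`.
#' @param x numeric 3-D array (for 2-D models, z extent 1).
#' @return foreground probability array of the valid output extent.
#' @export
unet_predict_patch <- function(model, x) {
  x <- array(x, dim = c(dim(x)[1:3], 1L))
  fw <- unet_forward(model, list(x), train = FALSE)
  pr <- fw$probs[[1]]
  array(pr[, , , 2], dim = dim(pr)[1:3])
}

#' Save / load a trained model
#'
#' Checkpoints embed the [arch_spec()] next to the weights so a model
#' can never be reloaded under a mismatched architecture.
#'
#' @param model a `unet`.
#' @param path checkpoint file path.
#' @return `load_model` returns the `unet`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet")) stop("not a unet checkpoint: ", path)
  model
}
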