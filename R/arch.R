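#' U-Net architecture specification
#'
#' Describes the encoder--decoder topology of a valid-convolution
#' (unpadded) U-Net with a fixed number of internal resolution levels.
#' All extent arithmetic (valid output size, receptive field, minimal
#' feasible input) is derived symbolically from this description, so the
#' printed network geometry can be verified without constructing weights.
#'
#' The default corresponds to the three-level network used throughout
#' this package: two unpadded 3-voxel convolutions per block on both the
#' contracting and expanding path, 2-fold max-pooling between encoder
#' levels, 2-fold nearest-neighbour upsampling followed by a
#' centre-cropped skip concatenation between decoder levels, and a final
#' 1-voxel convolution onto two output channels (foreground/background)
#' followed by a softmax. With these defaults the per-axis valid
#' reduction is 40 voxels and the maximum receptive field is 44 voxels
#' per axis.
#'
#' For `dimensionality = 2` the network operates on reformatted slices;
#' all arithmetic is per in-plane axis.
#'
#' @param dimensionality 2 or 3.
#' @param levels number of resolution levels (>= 2).
#' @param convs_per_block convolutions per block (encoder and decoder).
#' @param kernel_extent odd convolution kernel extent per axis.
#' @param pool_extent pooling/upsampling factor (>= 2).
#' @param base_channels feature channels at the first level; doubled at
#'   each deeper level. Small values keep CPU training tractable.
#' @param batch_norm logical; batch normalisation after every
#'   convolution (before the ReLU).
#' @return an object of class `arch_spec`.
#' @export
arch_spec <- function(dimensionality = 3, levels = 3, convs_per_block = 2,
                      kernel_extent = 3, pool_extent = 2,
                      base_channels = 32, batch_norm = TRUE) {
  stopifnot(dimensionality %in% c(2L, 3L))
  if (levels < 1) stop("levels must be >= 1")
  if (kernel_extent %% 2 != 1) stop("kernel_extent must be odd")
  if (pool_extent < 2) stop("pool_extent must be >= 2")
  if (convs_per_block < 1) stop("convs_per_block must be >= 1")
  if (base_channels < 1) stop("base_channels must be >= 1")
  structure(list(
    dimensionality = as.integer(dimensionality),
    levels = as.integer(levels),
    convs_per_block = as.integer(convs_per_block),
    kernel_extent = as.integer(kernel_extent),
    pool_extent = as.integer(pool_extent),
    base_channels = as.integer(base_channels),
    batch_norm = isTRUE(batch_norm),
    padding_mode = "valid",
    output_channels = 2L
  ), class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf(
    "<arch_spec> %d-D U-Net: %d levels, %d x %d^%d valid convs/block, pool %d, base width %d%s\n",
    x$dimensionality, x$levels, x$convs_per_block, x$kernel_extent,
    x$dimensionality, x$pool_extent, x$base_channels,
    if (x$batch_norm) ", batch norm" else ""))
  rf <- receptive_field(x)
  cat(sprintf("  valid reduction %d, receptive field %d voxels per axis\n",
              valid_reduction(x), rf[1]))
  invisible(x)
}

# Ordered layer list of the spatial-extent-changing operations, one axis.
# Types: "conv" (valid, kernel k), "pool" (factor p), "up" (factor p).
# The final 1x1 convolution is extent-neutral and omitted.
trace_layers <- function(spec) {
  k <- spec$kernel_extent
  p <- spec$pool_extent
  blk <- function() replicate(spec$convs_per_block,
                              list(type = "conv", k = k), simplify = FALSE)
  layers <- list()
  for (l in seq_len(spec$levels)) {
    layers <- c(layers, blk())
    if (l < spec$levels) layers <- c(layers, list(list(type = "pool", k = p)))
  }
  for (l in seq_len(spec$levels - 1)) {
    layers <- c(layers, list(list(type = "up", k = p)), blk())
  }
  layers
}

# Per-axis forward extent trace. Returns integer vector of extents after
# each layer, or stops with a diagnosis naming the failing layer.
trace_extent_1d <- function(spec, extent) {
  layers <- trace_layers(spec)
  e <- as.integer(extent)
  out <- integer(length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      e <- e - (ly$k - 1L)
      if (e < 1L)
        stop(sprintf("infeasible input extent %d: feature map vanishes at layer %d (valid conv %d)",
                     extent, i, ly$k), call. = FALSE)
    } else if (ly$type == "pool") {
      if (e %% ly$k != 0L)
        stop(sprintf("infeasible input extent %d: extent %d not divisible by pool factor %d at layer %d",
                     extent, e, ly$k, i), call. = FALSE)
      e <- e %/% ly$k
    } else {
      e <- e * ly$k
    }
    out[i] <- e
  }
  out
}

#' Valid output extent of the network for a given input extent
#'
#' Traces the per-layer spatial extents through the encoder (valid
#' convolutions shrink, pooling divides) and decoder (upsampling
#' multiplies, valid convolutions shrink) and returns the extent of the
#' classified centre region. Because all convolutions are unpadded, only
#' this centre can be classified; the remainder of the input acts as
#' context padding.
#'
#' @param spec an [arch_spec()].
#' @param input_extent integer vector of per-axis input extents
#'   (length 1 is recycled to the spec's dimensionality).
#' @return integer vector of per-axis output extents.
#' @examples
#' valid_output_size(arch_spec(3), c(72, 72, 56))  # 32 32 16
#' @export
valid_output_size <- function(spec, input_extent) {
  stopifnot(inherits(spec, "arch_spec"))
  ext <- as.integer(input_extent)
  if (length(ext) == 1L) ext <- rep(ext, spec$dimensionality)
  if (length(ext) != spec$dimensionality)
    stop("input_extent must have length 1 or the spec's dimensionality")
  vapply(ext, function(e) {
    tr <- trace_extent_1d(spec, e)
    tr[length(tr)]
  }, integer(1))
}

#' Total valid reduction per axis (input extent minus output extent)
#' @param spec an [arch_spec()].
#' @return a single integer; 40 for the default three-level network.
#' @export
valid_reduction <- function(spec) {
  ref <- min_input_for_output(spec, 1L)[1]
  as.integer(ref - valid_output_size(spec, ref)[1])
}

#' Maximum receptive field of the network, in voxels per axis
#'
#' The receptive field is the extent of the input region that can
#' influence the classification of a single output voxel. It is computed
#' by walking the traced layer list backwards with interval arithmetic:
#' a valid convolution of extent k widens the interval by k - 1, a
#' p-fold pooling maps output interval \[a, b\] to input \[p a, p b + p - 1\],
#' and a p-fold nearest-neighbour upsampling maps it to
#' \[floor(a / p), floor(b / p)\]. Because of the floor in the upsampling
#' step the interval length depends on the output voxel's index parity;
#' the maximum over output positions is returned, which is the quantity
#' conventionally reported for U-Nets.
#'
#' @param spec an [arch_spec()].
#' @return integer vector (length = dimensionality) of per-axis extents;
#'   44 per axis for the default three-level network.
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  layers <- rev(trace_layers(spec))
  period <- spec$pool_extent^(spec$levels - 1L)
  best <- 0L
  for (j in seq_len(period) - 1L) {
    a <- j; b <- j
    for (ly in layers) {
      if (ly$type == "conv") {
        b <- b + (ly$k - 1L)
      } else if (ly$type == "pool") {
        a <- ly$k * a
        b <- ly$k * b + (ly$k - 1L)
      } else {
        a <- a %/% ly$k
        b <- b %/% ly$k
      }
    }
    best <- max(best, b - a + 1L)
  }
  rep(as.integer(best), spec$dimensionality)
}

#' Receptive field in physical units
#'
#' Converts the voxel receptive field to millimetres for a given voxel
#' spacing; e.g. at 1 x 1 x 2 mm spacing the default 3-D network sees a
#' 44 x 44 x 88 mm context per classified voxel.
#'
#' @param spec an [arch_spec()].
#' @param spacing numeric vector of mm per voxel, one entry per axis.
#' @return numeric vector of per-axis receptive field extents in mm.
#' @export
receptive_field_mm <- function(spec, spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != spec$dimensionality)
    stop("spacing must have one entry per axis")
  if (any(spacing <= 0)) stop("spacing must be positive")
  receptive_field(spec) * spacing
}

#' Smallest feasible input extent for a desired output extent
#'
#' Inverse of [valid_output_size()]: the smallest input extent whose
#' traced output extent is at least `desired_output` while satisfying
#' every pooling divisibility constraint. Needed to size tiles and
#' padded slices for full-volume inference.
#'
#' @param spec an [arch_spec()].
#' @param desired_output integer vector of desired per-axis output
#'   extents (length 1 recycled).
#' @return integer vector of per-axis input extents.
#' @export
min_input_for_output <- function(spec, desired_output) {
  stopifnot(inherits(spec, "arch_spec"))
  des <- as.integer(desired_output)
  if (length(des) == 1L) des <- rep(des, spec$dimensionality)
  if (any(des < 1L)) stop("desired_output must be >= 1")
  vapply(des, function(d) {
    e <- d
    repeat {
      ok <- tryCatch({
        tr <- trace_extent_1d(spec, e)
        tr[length(tr)] >= d
      }, error = function(cond) FALSE)
      if (ok) return(as.integer(e))
      e <- e + 1L
      if (e > d + 10000L) stop("no feasible input extent found")  # unreachable in practice
    }
  }, integer(1))
}

#' Patch geometry for patch-based 3-D training and tiled inference
#'
#' A patch pairs an input context extent with the extent of the
#' classified centre region it yields under the valid-convolution
#' arithmetic of `arch`. The default 72 x 72 x 56 input classifies a
#' 32 x 32 x 16 centre; the surrounding margin (20 voxels per side on
#' each axis) is context only.
#'
#' @param input_extent integer triple (or pair for 2-D specs).
#' @param arch an [arch_spec()]; default 3-D spec.
#' @return an object of class `patch_spec` with fields `input_extent`,
#'   `output_extent` and per-axis per-side `margin`.
#' @export
patch_spec <- function(input_extent = c(72L, 72L, 56L), arch = arch_spec(3)) {
  input_extent <- as.integer(input_extent)
  out <- valid_output_size(arch, input_extent)
  margin <- (input_extent - out)
  if (any(margin %% 2L != 0L))
    stop("input minus output extent must be even on every axis")
  structure(list(
    input_extent = input_extent,
    output_extent = out,
    margin = margin %/% 2L
  ), class = "patch_spec")
}

#' @export
print.patch_spec <- function(x, ...) {
  cat(sprintf("<patch_spec> input %s -> classified centre %s (margin %s per side)\n",
              paste(x$input_extent, collapse = "x"),
              paste(x$output_extent, collapse = "x"),
              paste(x$margin, collapse = "x")))
  invisible(x)
}
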