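#' Configuration of the class-balancing training strategies
#'
#' Two strategies raise the foreground frequency seen during training of
#' a small-organ segmenter. For 2-D slice training, samples are drawn
#' only from a region of interest (ROI) around the target: the slice
#' range containing the gland extended by `slice_margin` slices per side
#' in view direction, plus -- for sagittal/coronal reformats, whose scan
#' range along z can be very large -- a `transverse_margin` restriction
#' above and below the gland. For 3-D patch training, every minibatch is
#' composed so that a fixed fraction of patches overlaps the gland with
#' their classified centre.
#'
#' @param view slice orientation: "axial", "coronal" or "sagittal".
#' @param slice_margin ROI margin in slices, per side, along the view
#'   axis (default 5).
#' @param transverse_margin extra z restriction in voxels above/below the
#'   gland, applied to sagittal/coronal views only (default 25).
#' @param patch_extent 3-D input patch extent (default 72 x 72 x 56,
#'   classifying a 32 x 32 x 16 centre under the default architecture).
#' @param fg_fraction fraction of patches per batch whose classified
#'   centre must overlap foreground (default 0.5).
#' @param batch_size patches (or slices) per minibatch.
#' @param rng_seed integer seed making all sampling reproducible.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(view = c("axial", "coronal", "sagittal"),
                            slice_margin = 5L, transverse_margin = 25L,
                            patch_extent = c(72L, 72L, 56L),
                            fg_fraction = 0.5, batch_size = 8L,
                            rng_seed = 1L) {
  view <- match.arg(view)
  if (fg_fraction < 0 || fg_fraction > 1)
    stop("fg_fraction must lie in [0, 1]")
  structure(list(view = view, slice_margin = as.integer(slice_margin),
                 transverse_margin = as.integer(transverse_margin),
                 patch_extent = as.integer(patch_extent),
                 fg_fraction = fg_fraction,
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "sampling_config")
}

view_axis <- function(view) {
  switch(view, sagittal = 1L, coronal = 2L, axial = 3L)
}

# per-axis foreground index range (1-based) of a mask
fg_range_axis <- function(voxels, axis) {
  range(which(apply(voxels, axis, any)))
}

#' Region of interest around a gland mask
#'
#' Along the view axis the ROI spans the gland's slice range extended by
#' `slice_margin` slices on each side; for sagittal/coronal views the
#' transverse (z) axis is additionally restricted to the gland's z range
#' extended by `transverse_margin` voxels; remaining axes keep their
#' full extent. All intervals are clipped to the volume.
#'
#' @param mask a nonempty [binary_mask()].
#' @param cfg a [sampling_config()].
#' @return an object of class `roi_box`: 0-based half-open intervals
#'   `lo`/`hi` per axis.
#' @export
compute_roi <- function(mask, cfg) {
  stopifnot(inherits(mask, "binary_mask"), inherits(cfg, "sampling_config"))
  if (!any(mask$voxels))
    stop("empty mask: case must be excluded from ROI training")
  d <- dim(mask$voxels)
  lo <- rep(0L, 3L); hi <- as.integer(d)
  va <- view_axis(cfg$view)
  r <- fg_range_axis(mask$voxels, va) - 1L  # 0-based
  lo[va] <- max(0L, r[1] - cfg$slice_margin)
  hi[va] <- min(d[va], r[2] + cfg$slice_margin + 1L)
  if (cfg$view %in% c("sagittal", "coronal")) {
    rz <- fg_range_axis(mask$voxels, 3L) - 1L
    lo[3] <- max(lo[3], rz[1] - cfg$transverse_margin)
    hi[3] <- min(hi[3], rz[2] + cfg$transverse_margin + 1L)
  }
  structure(list(lo = lo, hi = hi), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> [%s) x [%s) x [%s)\n",
              paste(c(x$lo[1], x$hi[1]), collapse = ", "),
              paste(c(x$lo[2], x$hi[2]), collapse = ", "),
              paste(c(x$lo[3], x$hi[3]), collapse = ", ")))
  invisible(x)
}

# extract the 2-D reformat of a volume at 0-based view-axis index k,
# cropped to the ROI box on the remaining axes
slice_2d <- function(voxels, view, k, roi = NULL) {
  d <- dim(voxels)
  lo <- if (is.null(roi)) rep(0L, 3L) else roi$lo
  hi <- if (is.null(roi)) as.integer(d) else roi$hi
  out <- switch(view,
    axial = voxels[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], k + 1L],
    coronal = voxels[(lo[1] + 1L):hi[1], k + 1L, (lo[3] + 1L):hi[3]],
    sagittal = voxels[k + 1L, (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3]])
  as.matrix(out)
}

#' Sample 2-D training slices from within the ROI
#'
#' Draws `n` view-axis indices uniformly at random from the ROI interval
#' and returns the corresponding reformatted image/label slice pairs
#' (cropped to the ROI on the non-view axes). A pure function of
#' (volume, mask, config, seed).
#'
#' @param vol a [volume_grid()].
#' @param mask the matching [binary_mask()].
#' @param cfg a [sampling_config()].
#' @param n number of slices to draw.
#' @param seed RNG seed; defaults to `cfg$rng_seed`.
#' @return list of `list(image, label, index)`; `index` is the 0-based
#'   view-axis index.
#' @export
sample_roi_slices <- function(vol, mask, cfg, n, seed = cfg$rng_seed) {
  stopifnot(inherits(vol, "volume_grid"))
  stop_unless_same_grid(vol, mask)
  roi <- compute_roi(mask, cfg)
  va <- view_axis(cfg$view)
  with_preserved_seed(seed, {
    ks <- roi$lo[va] + sample.int(roi$hi[va] - roi$lo[va], n,
                                  replace = TRUE) - 1L
    lapply(ks, function(k) {
      list(image = slice_2d(vol$voxels, cfg$view, k, roi),
           label = slice_2d(mask$voxels * 1, cfg$view, k, roi),
           index = k)
    })
  })
}

# fold an out-of-range 0-based index into [0, n) by mirror (symmetric,
# edge included) reflection
fold_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * n
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - 1L - i, i)
}

# extract a[start .. start+size-1] (0-based, any bounds) with mirror
# padding outside the array
extract_mirror <- function(a, start, size) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax)
    fold_index(start[ax] + seq_len(size[ax]) - 1L, d[ax]) + 1L)
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# embed a 2-D matrix centred in a mirror-padded matrix of extent target;
# returns list(m, off) with 0-based offset of the original within it
embed_mirror_2d <- function(m, target) {
  d <- dim(m)
  off <- (target - d) %/% 2L
  a <- array(m, dim = c(d, 1L))
  out <- extract_mirror(a, c(-off, 0L), c(target, 1L))
  list(m = array(out, dim = target), off = off)
}

#' Sample a class-balanced batch of 3-D patches
#'
#' Composes one minibatch so that exactly
#' `round(batch_size * fg_fraction)` patches (ties to even) have at
#' least one foreground voxel inside their classified centre region;
#' the remaining patches are placed uniformly over the volume with no
#' overlap requirement. Foreground placement samples a foreground voxel
#' and jitters the centre region within +/- its extent so that the voxel
#' stays inside. Input context beyond the volume is mirror-padded.
#'
#' @param vol a [volume_grid()].
#' @param mask the matching [binary_mask()].
#' @param cfg a [sampling_config()]; `patch_extent` is the input extent.
#' @param arch the [arch_spec()] used to derive the classified centre
#'   extent from `patch_extent`.
#' @param seed RNG seed; defaults to `cfg$rng_seed`.
#' @return list of `list(x, y, start, fg)`: raw-HU input patch, 0/1
#'   centre label patch, 0-based centre-region start, and whether the
#'   patch was drawn under the foreground constraint.
#' @export
sample_balanced_patches <- function(vol, mask, cfg, arch = arch_spec(3),
                                    seed = cfg$rng_seed) {
  stopifnot(inherits(vol, "volume_grid"))
  stop_unless_same_grid(vol, mask)
  ps <- patch_spec(cfg$patch_extent, arch)
  oe <- ps$output_extent
  d <- dim(vol$voxels)
  n_fg <- as.integer(round(cfg$batch_size * cfg$fg_fraction))
  if (n_fg > 0 && !any(mask$voxels))
    stop("no foreground in volume but fg_fraction > 0")
  fg_idx <- if (n_fg > 0) which(mask$voxels) else integer(0)

  with_preserved_seed(seed, {
    draw_patch <- function(s) {
      ctx_start <- s - ps$margin
      x <- extract_mirror(vol$voxels, ctx_start, ps$input_extent)
      y <- extract_mirror(mask$voxels * 1, s, oe)
      list(x = x, y = y, start = s)
    }
    out <- vector("list", cfg$batch_size)
    for (b in seq_len(cfg$batch_size)) {
      if (b <= n_fg) {
        v <- arrayInd(fg_idx[sample.int(length(fg_idx), 1L)], d)[1, ] - 1L
        s <- vapply(1:3, function(ax) {
          lo <- max(0L, v[ax] - oe[ax] + 1L)
          hi <- min(d[ax] - oe[ax], v[ax])
          as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
        }, integer(1))
        p <- draw_patch(s)
        p$fg <- TRUE
      } else {
        s <- vapply(1:3, function(ax) {
          span <- max(d[ax] - oe[ax], 0L)
          as.integer(sample.int(span + 1L, 1L) - 1L)
        }, integer(1))
        p <- draw_patch(s)
        p$fg <- FALSE
      }
      out[[b]] <- p
    }
    out
  })
}

#' Nested training subsets for the data-quantity experiment
#'
#' Shuffles the case list once (reproducibly) and takes prefixes, so
#' each smaller subset is contained in every larger one and learning
#' curves across sizes are comparable.
#'
#' @param case_ids character or integer vector of cases.
#' @param sizes subset sizes, each <= `length(case_ids)`.
#' @param seed shuffle seed.
#' @return named list of subsets, one per size (in the given order).
#' @export
select_training_subsets <- function(case_ids, sizes, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("subset sizes must be >= 1")
  if (max(sizes) > length(case_ids))
    stop("subset size ", max(sizes), " exceeds available cases (",
         length(case_ids), ")")
  shuffled <- with_preserved_seed(seed, sample(case_ids))
  out <- lapply(sizes, function(k) shuffled[seq_len(k)])
  names(out) <- as.character(sizes)
  out
}
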