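# Full-volume prediction. Valid convolutions make tiled inference exact:
# stitching the classified centres of overlapping contexts equals a
# single whole-volume pass, so tile size is purely a memory knob.

# Predict foreground probabilities for an arbitrary 3-D block.
# vox_norm: normalised full volume; s: 0-based block start; bs: block
# extent. Context is mirror-padded at volume borders.
predict_block <- function(model, vox_norm, s, bs) {
  spec <- model$spec
  if (spec$dimensionality == 3L) {
    Ib <- min_input_for_output(spec, bs)
  } else {
    Ib <- c(min_input_for_output(spec, bs[1:2]), bs[3])
  }
  red2 <- if (spec$dimensionality == 3L) rep(valid_reduction(spec) %/% 2L, 3L)
          else c(rep(valid_reduction(spec) %/% 2L, 2L), 0L)
  offb <- (Ib - bs) %/% 2L
  x <- extract_mirror(vox_norm, s - offb, Ib)
  p <- unet_predict_patch(model, x)
  cs <- offb - red2
  p[cs[1] + seq_len(bs[1]), cs[2] + seq_len(bs[2]), cs[3] + seq_len(bs[3]),
    drop = FALSE]
}

#' Full-volume prediction with a 2-D network
#'
#' Pushes every reformatted slice along the view axis through the
#' network and reassembles the per-slice foreground probabilities into a
#' volume aligned with the input. Slices larger than `tile_extent`
#' in-plane are tiled on their classified centres (exact for valid
#' convolutions); context beyond the slice is mirror-padded.
#'
#' @param model a 2-D `unet`.
#' @param vol a [volume_grid()] in Hounsfield units.
#' @param view "axial", "coronal" or "sagittal".
#' @param tile_extent in-plane output tile edge (voxels); `Inf` runs
#'   each slice in one pass.
#' @return a [prob_map()] on the input grid.
#' @export
predict_2d <- function(model, vol, view = c("axial", "coronal", "sagittal"),
                       tile_extent = Inf) {
  stopifnot(inherits(model, "unet"))
  view <- match.arg(view)
  if (model$spec$dimensionality != 2L) stop("model is not a 2-D network")
  d <- dim(vol$voxels)
  vox <- hu_normalize(vol$voxels)
  va <- view_axis(view)
  out <- array(NA_real_, dim = d)
  # in-plane extents of the reformatted slice, in volume-axis order
  ip <- setdiff(1:3, va)
  n <- d[ip]
  starts1 <- tile_starts(n[1], tile_extent)
  starts2 <- tile_starts(n[2], tile_extent)
  for (k in seq_len(d[va]) - 1L) {
    sl <- slice_2d(vox, view, k)
    sl3 <- array(sl, dim = c(dim(sl), 1L))
    psl <- matrix(NA_real_, n[1], n[2])
    for (s1 in starts1) for (s2 in starts2) {
      bs <- c(min(tile_extent, n[1] - s1), min(tile_extent, n[2] - s2))
      blk <- predict_block(model, sl3, c(s1, s2, 0L), c(bs, 1L))
      psl[s1 + seq_len(bs[1]), s2 + seq_len(bs[2])] <- blk[, , 1]
    }
    if (va == 3L) out[, , k + 1L] <- psl
    else if (va == 2L) out[, k + 1L, ] <- psl
    else out[k + 1L, , ] <- psl
  }
  prob_map(out, vol)
}

tile_starts <- function(n, te) {
  if (!is.finite(te) || te >= n) return(0L)
  as.integer(seq(0L, n - 1L, by = te))
}

#' Full-volume prediction with the 3-D network
#'
#' Tiles the volume with non-overlapping classified-centre blocks
#' (default 32 x 32 x 16), computes each from its mirror-padded input
#' context (default 72 x 72 x 56) and writes every voxel exactly once.
#'
#' @param model a 3-D `unet`.
#' @param vol a [volume_grid()] in Hounsfield units.
#' @param patch a [patch_spec()] giving the tile geometry.
#' @return a [prob_map()] on the input grid.
#' @export
predict_3d_tiled <- function(model, vol, patch = NULL) {
  stopifnot(inherits(model, "unet"))
  if (model$spec$dimensionality != 3L) stop("model is not a 3-D network")
  if (is.null(patch)) patch <- patch_spec(arch = model$spec)
  d <- dim(vol$voxels)
  vox <- hu_normalize(vol$voxels)
  oe <- patch$output_extent
  out <- array(NA_real_, dim = d)
  for (s3 in tile_starts(d[3], oe[3]))
    for (s2 in tile_starts(d[2], oe[2]))
      for (s1 in tile_starts(d[1], oe[1])) {
        s <- c(s1, s2, s3)
        bs <- pmin(oe, d - s)
        blk <- predict_block(model, vox, s, bs)
        out[s[1] + seq_len(bs[1]), s[2] + seq_len(bs[2]),
            s[3] + seq_len(bs[3])] <- blk
      }
  stopifnot(!anyNA(out))  # partition property: full coverage
  prob_map(out, vol)
}

#' Whole-volume single-pass prediction (reference path)
#'
#' Runs the network once on the entire mirror-padded volume. Memory
#' hungry; used to verify that tiled inference is exact.
#'
#' @param model a 3-D `unet`.
#' @param vol a [volume_grid()].
#' @return a [prob_map()] on the input grid.
#' @export
predict_3d_whole <- function(model, vol) {
  stopifnot(inherits(model, "unet"), model$spec$dimensionality == 3L)
  d <- dim(vol$voxels)
  vox <- hu_normalize(vol$voxels)
  prob_map(predict_block(model, vox, c(0L, 0L, 0L), d), vol)
}

#' Majority vote over orthogonal-view predictions
#'
#' Per-voxel 2-of-3 vote over binarised per-view masks. Permutation
#' invariant and monotone in each input.
#'
#' @param masks list of three [binary_mask()]s on identical grids
#'   (axial, coronal, sagittal predictions).
#' @return the fused [binary_mask()].
#' @export
ensemble_vote <- function(masks) {
  stopifnot(is.list(masks), length(masks) == 3L)
  lapply(masks, function(m) stopifnot(inherits(m, "binary_mask")))
  stop_unless_same_grid(masks[[1]], masks[[2]], "ensemble members")
  stop_unless_same_grid(masks[[1]], masks[[3]], "ensemble members")
  votes <- masks[[1]]$voxels + masks[[2]]$voxels + masks[[3]]$voxels
  binary_mask(votes >= 2L, masks[[1]])
}

#' Postprocessing configuration
#'
#' @param threshold binarisation threshold on the foreground
#'   probability (foreground iff p >= threshold).
#' @param connectivity 6 or 26 neighbourhood for 3-D components.
#' @return an object of class `postprocess_config`.
#' @export
postprocess_config <- function(threshold = 0.5, connectivity = 6L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(threshold = threshold,
                 connectivity = as.integer(connectivity)),
            class = "postprocess_config")
}

#' Binarise, keep the largest component, resample to the original grid
#'
#' The Dice-loss-trained networks output near-binary probabilities, so a
#' 0.5 threshold plus largest-connected-component selection (removing
#' small distant false positives) is sufficient postprocessing. Ties in
#' component size resolve to the component containing the lowest linear
#' voxel index. An empty binarisation yields an empty mask flagged via
#' `attr(, "empty_result")`, not an error.
#'
#' @param prob a [prob_map()].
#' @param cfg a [postprocess_config()].
#' @param original_grid optional geometry (see
#'   [resample_mask_to_grid()]) to resample the final mask onto by
#'   nearest neighbour.
#' @return a [binary_mask()] with attribute `empty_result`.
#' @export
postprocess <- function(prob, cfg = postprocess_config(),
                        original_grid = NULL) {
  stopifnot(inherits(prob, "prob_map"), inherits(cfg, "postprocess_config"))
  fg <- prob$voxels >= cfg$threshold
  empty <- !any(fg)
  if (!empty) {
    lab <- label_components_cpp(fg, dim(fg), cfg$connectivity)
    keep <- which.max(tabulate(lab))  # ties: first label = lowest index
    fg <- lab == keep
    dim(fg) <- dim(prob$voxels)
  }
  out <- binary_mask(fg, prob)
  if (!is.null(original_grid))
    out <- resample_mask_to_grid(out, original_grid)
  attr(out, "empty_result") <- empty
  out
}
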