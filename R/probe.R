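# Empirical receptive-field measurement by occlusion probing: perturb
# one input voxel at a time along a line through the volume centre and
# record which output voxels react. The maximum, over output voxels, of
# the number of probed inputs that influence it is the receptive field
# along that axis. Independent of the symbolic tracer, so the two can
# cross-check each other.

# Replace weights by their absolute values (biases zero, BN neutral,
# distinct per-channel final weights) so that signals cannot cancel and
# connectivity alone determines which outputs change.
make_probe_model <- function(spec, seed = 1L) {
  model <- build_unet(spec, seed = seed)
  for (nm in names(model$params)) {
    if (grepl("_w$", nm)) model$params[[nm]] <- abs(model$params[[nm]])
    if (grepl("_b$", nm)) model$params[[nm]][] <- 0
    if (grepl("_gamma$", nm)) model$params[[nm]][] <- 1
    if (grepl("_beta$", nm)) model$params[[nm]][] <- 0
  }
  for (nm in names(model$buffers)) {
    if (grepl("_running_mean$", nm)) model$buffers[[nm]][] <- 0
    if (grepl("_running_var$", nm)) model$buffers[[nm]][] <- 1
  }
  # make the two output channels react differently so the softmax
  # cannot mask a propagated change
  model$params$final_w[, , , , 2] <- 2 * model$params$final_w[, , , , 2]
  model
}

#' Measure the receptive field of a constructed network by occlusion
#'
#' Perturbs single input voxels of a zero volume along the probed axis
#' (other axes fixed at the centre), runs the network built from `spec`
#' with positive probe weights, and counts, per output voxel on the
#' central output line, how many probed inputs change it. Returns the
#' maximum count, the empirical receptive field along `axis`.
#'
#' @param spec an [arch_spec()].
#' @param axis probed axis (1 = x, 2 = y, 3 = z).
#' @param probe_extent input edge length (must be feasible; default 64).
#' @param base_channels probe network width (connectivity does not
#'   depend on width; 1 keeps it fast).
#' @param delta perturbation magnitude.
#' @param tol change-detection threshold.
#' @param seed probe-weight seed.
#' @return the measured receptive field in voxels (scalar).
#' @export
measure_receptive_field <- function(spec, axis = 1L, probe_extent = 64L,
                                    base_channels = 1L, delta = 10,
                                    tol = 1e-9, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  pspec <- spec
  pspec$base_channels <- as.integer(base_channels)
  model <- make_probe_model(pspec, seed = seed)
  ext <- if (spec$dimensionality == 3L) rep(probe_extent, 3L)
         else c(rep(probe_extent, 2L), 1L)
  if (spec$dimensionality == 2L && axis == 3L)
    stop("a 2-D network has no transverse receptive field to probe")
  x0 <- array(0, dim = ext)
  p0 <- unet_predict_patch(model, x0)
  oext <- dim(p0)
  oc <- pmax(oext %/% 2L, 1L)  # centre output line anchors
  ic <- pmax(ext %/% 2L, 1L)
  line_vals <- function(p) {
    switch(axis, p[, oc[2], oc[3]], p[oc[1], , oc[3]], p[oc[1], oc[2], ])
  }
  base_line <- line_vals(p0)
  affects <- matrix(FALSE, nrow = ext[axis], ncol = oext[axis])
  for (v in seq_len(ext[axis])) {
    x <- x0
    pos <- ic; pos[axis] <- v
    x[pos[1], pos[2], pos[3]] <- delta
    p <- unet_predict_patch(model, x)
    affects[v, ] <- abs(line_vals(p) - base_line) > tol
  }
  max(colSums(affects))
}
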