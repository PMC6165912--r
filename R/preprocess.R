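# Preprocessing to the training resolution. Clinical head-and-neck
# scans come at ~1 mm in-plane but 2 or 3 mm slice spacing, so volumes
# are resampled along the transverse (z) axis only; in-plane detail is
# left untouched.

lanczos_kernel <- function(t, a = 3) {
  w <- ifelse(abs(t) < 1e-12, 1,
              a * sin(pi * t) * sin(pi * t / a) / (pi^2 * t^2))
  w[abs(t) >= a] <- 0
  w
}

#' Resample a volume along the transverse axis
#'
#' 1-D Lanczos interpolation (support size a = 3) along z only. The
#' first output slice sits at the physical position of the first input
#' slice and the output has `floor(physical_z_extent / target) + 1`
#' slices, so the grid stays origin-anchored and the physical extent
#' changes by less than one target spacing. Kernel weights are
#' renormalised to sum to one per output sample (constants are
#' preserved exactly); samples beyond the volume are clamped to the
#' edge slices. Lanczos ringing is kept as-is (no intensity clamping).
#'
#' @param vol a [volume_grid()].
#' @param target_z_spacing desired slice spacing in mm.
#' @return a [volume_grid()] with unchanged in-plane geometry.
#' @export
resample_transverse <- function(vol, target_z_spacing) {
  stopifnot(inherits(vol, "volume_grid"))
  if (target_z_spacing <= 0) stop("target_z_spacing must be > 0")
  nz <- dim(vol$voxels)[3]
  zsp <- vol$spacing[3]
  if (abs(zsp - target_z_spacing) < 1e-9) return(vol)
  if (nz == 1L)
    stop("cannot interpolate a single-slice volume to a finer spacing")
  extent <- (nz - 1) * zsp
  n_out <- floor(extent / target_z_spacing) + 1L
  # input-index positions (0-based) of the output slices
  s <- (seq_len(n_out) - 1) * target_z_spacing / zsp
  base <- floor(s)
  W <- matrix(0, nrow = n_out, ncol = nz)
  for (off in -2:3) {
    j <- base + off                       # sample index, may be off-grid
    wgt <- lanczos_kernel(s - j)
    jc <- pmin(pmax(j, 0), nz - 1)        # clamp-to-edge extension
    for (k in seq_len(n_out))
      if (wgt[k] != 0) W[k, jc[k] + 1] <- W[k, jc[k] + 1] + wgt[k]
  }
  W <- W / rowSums(W)
  d <- dim(vol$voxels)
  m <- matrix(vol$voxels, nrow = d[1] * d[2], ncol = d[3])
  out <- m %*% t(W)
  volume_grid(array(out, dim = c(d[1], d[2], n_out)),
              c(vol$spacing[1:2], target_z_spacing), vol$origin)
}

# nearest source index (0-based) along one axis for each target centre;
# equidistant ties resolve to the lower index
nearest_index_1d <- function(n_t, sp_t, or_t, n_s, sp_s, or_s) {
  phys <- or_t + (seq_len(n_t) - 1) * sp_t
  u <- (phys - or_s) / sp_s
  j <- ceiling(u - 0.5)
  pmin(pmax(j, 0), n_s - 1)
}

#' Resample a mask onto another grid by nearest neighbour
#'
#' Every output voxel takes the value of the input voxel whose physical
#' centre is nearest (per axis, grids being axis-aligned); equidistant
#' ties resolve to the lower index. Used to bring network predictions
#' back to the original image resolution.
#'
#' @param mask a [binary_mask()].
#' @param target a [volume_grid()], [binary_mask()] or list with
#'   `extent`, `spacing`, `origin` describing the target geometry.
#' @return a [binary_mask()] on the target geometry.
#' @export
resample_mask_to_grid <- function(mask, target) {
  stopifnot(inherits(mask, "binary_mask"))
  geo <- as_geometry(target)
  d <- dim(mask$voxels)
  ix <- nearest_index_1d(geo$extent[1], geo$spacing[1], geo$origin[1],
                         d[1], mask$spacing[1], mask$origin[1]) + 1
  iy <- nearest_index_1d(geo$extent[2], geo$spacing[2], geo$origin[2],
                         d[2], mask$spacing[2], mask$origin[2]) + 1
  iz <- nearest_index_1d(geo$extent[3], geo$spacing[3], geo$origin[3],
                         d[3], mask$spacing[3], mask$origin[3]) + 1
  binary_mask(mask$voxels[ix, iy, iz, drop = FALSE], geo$spacing,
              geo$origin, laterality = mask$laterality)
}

as_geometry <- function(target) {
  if (inherits(target, c("volume_grid", "binary_mask", "prob_map")))
    list(extent = dim(target$voxels), spacing = target$spacing,
         origin = target$origin)
  else if (is.list(target) &&
           all(c("extent", "spacing", "origin") %in% names(target)))
    target
  else stop("target must be a grid object or list(extent, spacing, origin)")
}

#' Patient body mask for treatment-couch removal
#'
#' The couch is a high-density slab disjoint from the patient, so a
#' simple segmentation suffices: threshold above `threshold` HU, keep
#' the largest 6-connected 3-D component, and fill in-plane holes (air
#' cavities) slice by slice. Apply with [apply_body_mask()] to blank
#' everything outside the patient.
#'
#' @param vol a [volume_grid()] in Hounsfield units.
#' @param threshold body threshold in HU.
#' @return a [binary_mask()] of the patient body.
#' @export
remove_couch <- function(vol, threshold = -300) {
  stopifnot(inherits(vol, "volume_grid"))
  fg <- vol$voxels > threshold
  if (!any(fg)) stop("no body found: no voxels above ", threshold, " HU")
  lab <- label_components_cpp(fg, dim(fg), 6L)
  counts <- tabulate(lab)
  body <- lab == which.max(counts)
  dim(body) <- dim(fg)
  body <- fill_holes_inplane(body)
  binary_mask(body, vol)
}

# fill in-plane (per-axial-slice) holes: background 4-connected regions
# not touching the slice border become foreground
fill_holes_inplane <- function(body) {
  d <- dim(body)
  for (k in seq_len(d[3])) {
    sl <- body[, , k]
    inv <- array(!sl, dim = c(d[1], d[2], 1L))
    lab <- label_components_cpp(inv, dim(inv), 6L)
    dim(lab) <- d[1:2]
    border_labs <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    border_labs <- border_labs[border_labs > 0]
    holes <- !sl & !(lab %in% border_labs)
    dim(holes) <- d[1:2]
    body[, , k] <- sl | holes
  }
  body
}

#' @rdname remove_couch
#' @param mask the body mask from `remove_couch`.
#' @param fill HU value outside the mask (air).
#' @export
apply_body_mask <- function(vol, mask, fill = -1024) {
  stopifnot(inherits(vol, "volume_grid"), inherits(mask, "binary_mask"))
  stop_unless_same_grid(vol, mask)
  v <- vol$voxels
  v[!mask$voxels] <- fill
  volume_grid(v, vol$spacing, vol$origin)
}

#' Mirror a volume (and mask) across the sagittal midplane
#'
#' Flips the patient left--right axis, turning a right-sided structure
#' into a left-sided one. This doubles the usable references when a
#' network is trained on one laterality only. Applying the operation
#' twice restores the input.
#'
#' @param vol a [volume_grid()].
#' @param mask optional [binary_mask()] mirrored jointly.
#' @return the mirrored volume, or `list(volume, mask)` when a mask is
#'   given; mask laterality is swapped.
#' @export
mirror_sagittal <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "volume_grid"))
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  mv <- volume_grid(flip(vol$voxels), vol$spacing, vol$origin)
  if (is.null(mask)) return(mv)
  stopifnot(inherits(mask, "binary_mask"))
  lat <- switch(mask$laterality, left = "right", right = "left",
                "unspecified")
  list(volume = mv,
       mask = binary_mask(flip(mask$voxels), mask$spacing, mask$origin,
                          laterality = lat))
}
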