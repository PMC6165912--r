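#' Scalar 3-D image on a physical grid
#'
#' The unit of all I/O and inference: a 3-D array of Hounsfield-unit
#' voxels together with its physical geometry. Arrays are always stored
#' in (x, y, z) order with x the patient left--right axis, y
#' anterior--posterior and z the transverse (head--foot) axis along
#' which CT slices are stacked.
#'
#' @param voxels numeric 3-D array (Hounsfield units).
#' @param spacing numeric triple, mm per voxel along (x, y, z); all > 0.
#' @param origin physical coordinate (mm) of voxel (1,1,1)'s centre.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array, got ", length(dim(voxels)), " dims")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  if (any(dim(voxels) < 1L)) stop("all extents must be >= 1")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm, origin (%s), HU range [%.0f, %.0f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary segmentation mask on a volume grid
#'
#' @param voxels logical (or 0/1) 3-D array.
#' @param spacing,origin grid geometry, as in [volume_grid()]; a
#'   `volume_grid` or `binary_mask` may be given as `spacing` to copy
#'   its geometry.
#' @param laterality one of "left", "right", "unspecified".
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                        laterality = c("unspecified", "left", "right")) {
  if (inherits(spacing, c("volume_grid", "binary_mask", "prob_map"))) {
    origin <- spacing$origin
    spacing <- spacing$spacing
  }
  laterality <- match.arg(laterality)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), laterality = laterality),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels @ %s mm, %d foreground (%s)\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$voxels), x$laterality))
  invisible(x)
}

#' Foreground-probability map on a volume grid
#'
#' @param voxels numeric 3-D array with values in \[0, 1\].
#' @param spacing,origin geometry as in [binary_mask()].
#' @return an object of class `prob_map`.
#' @export
prob_map <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (inherits(spacing, c("volume_grid", "binary_mask", "prob_map"))) {
    origin <- spacing$origin
    spacing <- spacing$spacing
  }
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (min(voxels) < -1e-9 || max(voxels) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "prob_map")
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_unless_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " must live on identical grids (extents, spacing, origin)")
  invisible(TRUE)
}
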