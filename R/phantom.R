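#' Configuration of the synthetic CT head phantom
#'
#' The phantom emulates, at desk scale, the features of a planning CT
#' that the pipeline must cope with: an elliptical soft-tissue body
#' cross-section surrounded by air, one ellipsoidal parotid-like target
#' per side placed laterally (superficially) inside the body with low
#' contrast to the surrounding tissue, optional distractor blobs of
#' gland-like intensity near the midline, an optional treatment-couch
#' slab below the body, optional bright/dark streak pairs through the
#' gland region (dental-artifact stand-in), anisotropic voxel spacing,
#' and Gaussian HU noise.
#'
#' Intensity palette (HU): air -1024, soft tissue 40, gland
#' 40 + `gland_contrast` (default 60), couch 200, distractors uniform
#' in `distractor_hu`. Noise defaults to 10 HU, a typical quantum-noise
#' level for soft tissue in planning CT. Geometry ranges are drawn per
#' phantom from the configured intervals (mm).
#'
#' @param extents voxel triple.
#' @param spacing mm triple; 1 x 1 x 2 mm by default (2 or 3 mm slices
#'   are the clinical reality; 2 mm is the training resolution).
#' @param body_semiaxes_mm in-plane semi-axes of the body ellipse.
#' @param body_hu,gland_contrast soft-tissue mean HU and gland offset.
#' @param gland_radii_mm 2-column matrix (min, max) of per-axis gland
#'   semi-axis ranges in mm, rows = (x, y, z).
#' @param gland_offset_mm lateral (x) distance range of gland centres
#'   from the midline.
#' @param n_distractors number of gland-like blobs near the midline.
#' @param distractor_radii_mm,distractor_hu distractor geometry/intensity.
#' @param couch logical; add a high-density slab below the body.
#' @param artifact_streaks logical; add streak pairs through the glands.
#' @param noise_sigma additive Gaussian noise (HU).
#' @param seed integer; the phantom is a pure function of the config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(extents = c(96L, 96L, 48L),
                           spacing = c(1, 1, 2),
                           body_semiaxes_mm = c(40, 34),
                           body_hu = 40,
                           gland_contrast = 20,
                           gland_radii_mm = rbind(x = c(8, 11),
                                                  y = c(7, 10),
                                                  z = c(9, 14)),
                           gland_offset_mm = c(22, 26),
                           n_distractors = 0L,
                           distractor_radii_mm = c(5, 9),
                           distractor_hu = c(55, 65),
                           couch = FALSE,
                           artifact_streaks = FALSE,
                           noise_sigma = 10,
                           seed = 1L) {
  cfg <- list(extents = as.integer(extents), spacing = as.numeric(spacing),
              body_semiaxes_mm = body_semiaxes_mm, body_hu = body_hu,
              gland_contrast = gland_contrast,
              gland_radii_mm = gland_radii_mm,
              gland_offset_mm = gland_offset_mm,
              n_distractors = as.integer(n_distractors),
              distractor_radii_mm = distractor_radii_mm,
              distractor_hu = distractor_hu,
              couch = isTRUE(couch),
              artifact_streaks = isTRUE(artifact_streaks),
              noise_sigma = noise_sigma, seed = as.integer(seed))
  if (any(cfg$extents < 8L)) stop("extents too small for a phantom")
  if (any(cfg$spacing <= 0)) stop("spacing must be positive")
  structure(cfg, class = "phantom_config")
}

with_preserved_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# physical voxel-centre coordinate vectors, mm
phys_axes <- function(extents, spacing) {
  lapply(1:3, function(a) (seq_len(extents[a]) - 1) * spacing[a])
}

ellipsoid_mask <- function(ax, center, radii) {
  ex <- (ax[[1]] - center[1])^2 / radii[1]^2
  ey <- (ax[[2]] - center[2])^2 / radii[2]^2
  ez <- (ax[[3]] - center[3])^2 / radii[3]^2
  outer(outer(ex, ey, `+`), ez, `+`) <= 1
}

#' Generate one synthetic head phantom
#'
#' @param cfg a [phantom_config()].
#' @return a list of class `phantom` with elements `volume`
#'   ([volume_grid()]), `left` and `right` (exact rasterised gland
#'   [binary_mask()]s) and `meta` (construction ground truth: logical
#'   arrays `body`, `couch`, `distractors` and the noiseless volume's
#'   gland/body HU palette).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_preserved_seed(cfg$seed, {
    ext <- cfg$extents; sp <- cfg$spacing
    ax <- phys_axes(ext, sp)
    cx <- (ext[1] - 1) * sp[1] / 2
    cy <- (ext[2] - 1) * sp[2] / 2
    cz <- (ext[3] - 1) * sp[3] / 2

    ex2 <- (ax[[1]] - cx)^2 / cfg$body_semiaxes_mm[1]^2
    ey2 <- (ax[[2]] - cy)^2 / cfg$body_semiaxes_mm[2]^2
    body2d <- outer(ex2, ey2, `+`) <= 1
    body <- array(body2d, dim = ext)  # body spans all slices

    vol <- array(-1024, dim = ext)
    vol[body] <- cfg$body_hu

    rr <- function(rng) stats::runif(1, rng[1], rng[2])
    gland_one <- function(side) {
      radii <- c(rr(cfg$gland_radii_mm[1, ]), rr(cfg$gland_radii_mm[2, ]),
                 rr(cfg$gland_radii_mm[3, ]))
      center <- c(cx + side * rr(cfg$gland_offset_mm),
                  cy + stats::runif(1, -4, 4),
                  cz + stats::runif(1, -0.1, 0.1) * (ext[3] * sp[3]))
      m <- ellipsoid_mask(ax, center, radii)
      if (!any(m)) stop("phantom config error: gland rasterises to nothing")
      if (any(m & !body))
        stop("phantom config error: gland extends outside the body ",
             "(offset/radii too large for the body ellipse)")
      list(mask = m, center = center, radii = radii)
    }
    gl <- gland_one(+1)   # patient left = +x
    gr <- gland_one(-1)   # right gland generated explicitly, not mirrored
    vol[gl$mask] <- cfg$body_hu + cfg$gland_contrast
    vol[gr$mask] <- cfg$body_hu + cfg$gland_contrast

    distract <- array(FALSE, dim = ext)
    if (cfg$n_distractors > 0) {
      glands <- gl$mask | gr$mask
      placed <- 0L; tries <- 0L
      while (placed < cfg$n_distractors && tries < 100L) {
        tries <- tries + 1L
        radii <- rep(rr(cfg$distractor_radii_mm), 3)
        center <- c(cx + stats::runif(1, -0.25, 0.25) * cfg$body_semiaxes_mm[1],
                    cy + stats::runif(1, -0.3, 0.3) * cfg$body_semiaxes_mm[2],
                    stats::runif(1, 0.2, 0.8) * (ext[3] - 1) * sp[3])
        m <- ellipsoid_mask(ax, center, radii)
        if (!any(m) || any(m & !body) || any(m & glands) || any(m & distract))
          next
        vol[m] <- stats::runif(1, cfg$distractor_hu[1], cfg$distractor_hu[2])
        distract <- distract | m
        placed <- placed + 1L
      }
      if (placed < cfg$n_distractors)
        warning("placed only ", placed, " of ", cfg$n_distractors,
                " distractors")
    }

    couch <- array(FALSE, dim = ext)
    if (cfg$couch) {
      ymax_body <- cy + cfg$body_semiaxes_mm[2]
      y_lo <- ymax_body + 4; y_hi <- y_lo + 6       # 4 mm air gap, 6 mm slab
      xw <- 0.85 * (ext[1] - 1) * sp[1] / 2
      sel_y <- ax[[2]] >= y_lo & ax[[2]] < y_hi
      sel_x <- abs(ax[[1]] - cx) <= xw
      if (!any(sel_y))
        stop("phantom config error: no room for the couch below the body")
      couch[sel_x, sel_y, ] <- TRUE
      vol[couch] <- 200
    }

    if (cfg$artifact_streaks) {
      for (g in list(gl, gr)) {
        kz <- which(abs(ax[[3]] - g$center[3]) <= g$radii[3])
        for (k in kz) {
          theta <- stats::runif(1, 0, pi)
          tt <- seq(-45, 45, by = 0.5)
          for (sgn in c(1, -1)) {
            px <- g$center[1] + tt * cos(theta + (sgn < 0) * 0.2)
            py <- g$center[2] + tt * sin(theta + (sgn < 0) * 0.2)
            i <- round(px / sp[1]) + 1; j <- round(py / sp[2]) + 1
            ok <- i >= 1 & i <= ext[1] & j >= 1 & j <= ext[2]
            idx <- cbind(i[ok], j[ok], k)
            vol[idx] <- vol[idx] + sgn * 150
          }
        }
      }
    }

    if (cfg$noise_sigma > 0)
      vol <- vol + array(stats::rnorm(prod(ext), 0, cfg$noise_sigma),
                         dim = ext)

    vg <- volume_grid(vol, sp)
    structure(list(
      volume = vg,
      left = binary_mask(gl$mask, vg, laterality = "left"),
      right = binary_mask(gr$mask, vg, laterality = "right"),
      meta = list(body = body, couch = couch, distractors = distract,
                  gland = list(left = gl[c("center", "radii")],
                               right = gr[c("center", "radii")]),
                  hu = list(body = cfg$body_hu,
                            gland = cfg$body_hu + cfg$gland_contrast))
    ), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, glands %d (L) / %d (R) voxels\n",
              paste(dim(x$volume$voxels), collapse = "x"),
              sum(x$left$voxels), sum(x$right$voxels)))
  invisible(x)
}

#' Generate a phantom cohort and dataset manifest
#'
#' Draws `n` phantoms with per-case geometry sampled from the config's
#' ranges. With `out_dir` set, writes one volume and two mask files per
#' case (NIfTI, compressed) plus a `manifest.csv` with columns
#' `case_id, volume, mask_left, mask_right`; otherwise the phantoms are
#' returned in memory.
#'
#' @param n number of cases.
#' @param cfg a [phantom_config()]; its `seed` is ignored in favour of
#'   per-case seeds derived from `seed`.
#' @param seed cohort seed.
#' @param out_dir output directory, or `NULL` for an in-memory cohort.
#' @return `list(phantoms = <list or NULL>, manifest = <data.frame>)`.
#' @export
generate_cohort <- function(n, cfg = phantom_config(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(n >= 1)
  case_seeds <- with_preserved_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("case%03d", seq_len(n))
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg; ci$seed <- case_seeds[i]
    phantoms[[i]] <- generate_phantom(ci)
  }
  if (is.null(out_dir)) {
    manifest <- data.frame(case_id = ids, stringsAsFactors = FALSE)
    return(list(phantoms = phantoms, manifest = manifest))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vol_p <- file.path(out_dir, paste0(ids, ".nii.gz"))
  ml_p <- file.path(out_dir, paste0(ids, "_parotid_l.nii.gz"))
  mr_p <- file.path(out_dir, paste0(ids, "_parotid_r.nii.gz"))
  for (i in seq_len(n)) {
    write_volume(phantoms[[i]]$volume, vol_p[i])
    write_mask(phantoms[[i]]$left, ml_p[i])
    write_mask(phantoms[[i]]$right, mr_p[i])
  }
  manifest <- data.frame(case_id = ids, volume = vol_p, mask_left = ml_p,
                         mask_right = mr_p, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(phantoms = phantoms, manifest = manifest)
}
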