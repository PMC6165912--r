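# Shared fixtures. Expensive objects (phantom cohorts, trained models)
# are built lazily once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# a compact phantom world that keeps unit tests fast; geometry scaled
# to a 64 x 64 x 32 grid at 1 x 1 x 2 mm
small_phantom_config <- function(seed = 1L, ...) {
  defaults <- list(
    extents = c(64L, 64L, 32L),
    body_semiaxes_mm = c(26, 22),
    gland_radii_mm = rbind(x = c(6, 8), y = c(5, 7), z = c(6, 9)),
    gland_offset_mm = c(13, 16),
    seed = seed)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

small_phantom <- function(seed = 1L, ...) {
  memo(paste0("ph_", seed, "_", paste(c(...), collapse = "_")),
       function() generate_phantom(small_phantom_config(seed = seed, ...)))
}

# random small mask pair on a shared grid (for metric oracles)
random_mask_pair <- function(seed, extent = c(8L, 8L, 6L),
                             spacing = c(1, 1.2, 2)) {
  set.seed(seed)
  repeat {
    a <- array(runif(prod(extent)) < 0.35, dim = extent)
    b <- array(runif(prod(extent)) < 0.35, dim = extent)
    if (any(a) && any(b)) break
  }
  list(X = binary_mask(a, spacing), Y = binary_mask(b, spacing))
}

# brute-force signed-distance oracles implementing the surface-distance
# definition directly (no distance transform, no shared code with the
# package fast path)
oracle_border <- function(voxels) {
  d <- dim(voxels)
  idx <- which(voxels, arr.ind = TRUE)
  is_border <- apply(idx, 1, function(v) {
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + dd
      if (any(w < 1L) || any(w > d)) return(TRUE)
      if (!voxels[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  })
  idx[is_border, , drop = FALSE]
}

oracle_signed_dist <- function(v, mask, spacing) {
  bd <- oracle_border(mask)
  dp <- sweep(bd, 2, v, `-`)
  dp <- sweep(dp, 2, spacing, `*`)
  mag <- sqrt(min(rowSums(dp^2)))
  if (mask[v[1], v[2], v[3]]) -mag else mag
}

oracle_assd <- function(X, Y, spacing) {
  bx <- oracle_border(X); by <- oracle_border(Y)
  sx <- sum(apply(bx, 1, oracle_signed_dist, mask = Y, spacing = spacing))
  sy <- sum(apply(by, 1, oracle_signed_dist, mask = X, spacing = spacing))
  (sx - sy) / (nrow(bx) + nrow(by))
}

oracle_dice <- function(X, Y) {
  2 * sum(X & Y) / (sum(X) + sum(Y))
}
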