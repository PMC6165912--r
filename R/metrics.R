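#' Dice similarity coefficient
#'
#' `DSC(X, Y) = 2 |X intersect Y| / (|X| + |Y|)` over voxel sets.
#' Symmetric; 1 for identical nonempty masks, 0 for disjoint ones. If
#' exactly one mask is empty the result is 0; two empty masks are an
#' undefined input and raise an error.
#'
#' @param X,Y [binary_mask()]s on identical grids.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(X, Y) {
  stopifnot(inherits(X, "binary_mask"), inherits(Y, "binary_mask"))
  stop_unless_same_grid(X, Y)
  nx <- sum(X$voxels); ny <- sum(Y$voxels)
  if (nx == 0 && ny == 0) stop("Dice undefined: both masks empty")
  if (nx == 0 || ny == 0) return(0)
  2 * sum(X$voxels & Y$voxels) / (nx + ny)
}

#' Border voxels of a mask
#'
#' A foreground voxel belongs to the border if any of its six
#' face-adjacent neighbours is background or lies outside the volume
#' (the volume boundary counts as background).
#'
#' @param X a nonempty [binary_mask()].
#' @return an object of class `border_set`: `idx`, an n x 3 matrix of
#'   1-based voxel indices, plus the grid `spacing` and `origin`.
#' @export
border_voxels <- function(X) {
  stopifnot(inherits(X, "binary_mask"))
  v <- X$voxels
  if (!any(v)) stop("border undefined for an empty mask")
  d <- dim(v)
  pad <- array(FALSE, dim = d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- v
  interior <-
    pad[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  border <- v & !interior
  structure(list(idx = which(border, arr.ind = TRUE),
                 spacing = X$spacing, origin = X$origin),
            class = "border_set")
}

border_phys <- function(bs) {
  sweep(sweep(bs$idx - 1, 2, bs$spacing, `*`), 2, bs$origin, `+`)
}

#' Signed Euclidean distance of a voxel to a mask's border
#'
#' Magnitude: minimum physical (mm) centre-to-centre distance from the
#' voxel to the border voxels of `Y`. Sign: positive outside `Y`,
#' negative inside it; border voxels of `Y` get 0.
#'
#' @param x 1-based voxel index triple on `Y`'s grid.
#' @param Y a nonempty [binary_mask()].
#' @return signed distance in mm.
#' @export
signed_distance <- function(x, Y) {
  stopifnot(inherits(Y, "binary_mask"))
  bs <- border_voxels(Y)
  xphys <- matrix((x - 1) * Y$spacing + Y$origin, nrow = 1)
  mag <- min_pairwise_dist_cpp(xphys, border_phys(bs))
  s <- if (Y$voxels[x[1], x[2], x[3]]) -1 else 1
  d <- s * mag
  if (d == 0) 0 else d  # normalise -0
}

#' Average signed surface distance (ASSD)
#'
#' For prediction `X` against reference `Y`:
#' `ASSD(X, Y) = (sum_{x in dX} d(x, Y) - sum_{y in dY} d(y, X)) /
#' (|dX| + |dY|)`, where `d(., M)` is the signed distance of a voxel to
#' the border of mask `M` (positive outside `M`, negative inside).
#' Overestimation of the reference yields positive values,
#' underestimation negative ones; identical masks give 0. Distances are
#' physical (mm) between voxel centres.
#'
#' @param X prediction, a nonempty [binary_mask()].
#' @param Y reference, a nonempty [binary_mask()] on the same grid.
#' @return signed distance in mm.
#' @export
assd <- function(X, Y) {
  stopifnot(inherits(X, "binary_mask"), inherits(Y, "binary_mask"))
  stop_unless_same_grid(X, Y)
  if (!any(X$voxels) || !any(Y$voxels))
    stop("ASSD undefined for empty masks")
  bx <- border_voxels(X); by <- border_voxels(Y)
  px <- border_phys(bx); py <- border_phys(by)
  dxy <- min_pairwise_dist_cpp(px, py)    # |d(x, Y)| for x in dX
  dyx <- min_pairwise_dist_cpp(py, px)    # |d(y, X)| for y in dY
  in_y <- Y$voxels[bx$idx]                # sign of d(x, Y)
  in_x <- X$voxels[by$idx]                # sign of d(y, X)
  sx <- sum(ifelse(in_y, -dxy, dxy))
  sy <- sum(ifelse(in_x, -dyx, dyx))
  (sx - sy) / (nrow(bx$idx) + nrow(by$idx))
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided test on paired per-case metrics at level `alpha`.
#' Zero-difference pairs are dropped; the exact null distribution is
#' used for n <= 25 without ties, otherwise the normal approximation
#' with tie and continuity correction. If all differences are zero the
#' result is "not significant" with p = 1 by convention.
#'
#' @param a,b equal-length paired samples (same cases, two methods).
#' @param alpha significance level.
#' @return `list(statistic, p, significant, n_effective)`.
#' @export
wilcoxon_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("samples must be paired (equal length)")
  if (length(a) < 5) stop("need at least 5 pairs")
  diffs <- a - b
  nz <- diffs[diffs != 0]
  if (length(nz) == 0)
    return(list(statistic = NA_real_, p = 1, significant = FALSE,
                n_effective = 0L))
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided", mu = 0,
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, n_effective = length(nz))
}

#' Evaluate predictions against references
#'
#' @param preds,refs equal-length lists of [binary_mask()]s (same
#'   grids pairwise); empty predictions get Dice against the reference
#'   and a missing ASSD.
#' @param case_ids optional case labels.
#' @return a data.frame with columns `case_id`, `dice`, `assd_mm`,
#'   `empty_result`.
#' @export
evaluate_cases <- function(preds, refs, case_ids = NULL) {
  stopifnot(length(preds) == length(refs))
  if (is.null(case_ids)) case_ids <- sprintf("case%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    p <- preds[[i]]; r <- refs[[i]]
    empty <- !any(p$voxels)
    data.frame(
      case_id = case_ids[i],
      dice = if (empty) 0 else dice(p, r),
      assd_mm = if (empty) NA_real_ else assd(p, r),
      empty_result = empty,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Training-set-size experiment
#'
#' Trains one 3-D patch-based model per nested subset size, evaluates
#' all of them on a fixed evaluation set (full-volume tiled inference +
#' largest-component postprocessing), and compares adjacent sizes with
#' the paired Wilcoxon signed-rank test. Fully seeded; a failed
#' training for one size is recorded and the remaining sizes continue.
#'
#' @param cases list of `list(volume, mask)` training cases.
#' @param sizes subset sizes (see [select_training_subsets()]).
#' @param eval_cases list of `list(volume, mask)` evaluation cases.
#' @param train_config list of training settings: `arch`
#'   ([arch_spec()]), `sampling` ([sampling_config()]), `steps`, `lr`.
#' @param seed experiment seed (subset shuffle, weights, sampling).
#' @param alpha level for the adjacent-size comparisons (unadjusted).
#' @return `list(records = <per-size data.frames>, medians,
#'   comparisons = <data.frame>, errors)`.
#' @export
run_size_experiment <- function(cases, sizes, eval_cases,
                                train_config = list(), seed = 1L,
                                alpha = 0.05) {
  tc <- utils::modifyList(list(
    arch = arch_spec(3, base_channels = 4),
    sampling = sampling_config(patch_extent = c(56L, 56L, 48L),
                               batch_size = 4L),
    steps = 150L, lr = 3e-3), train_config)
  subsets <- select_training_subsets(seq_along(cases), sizes, seed = seed)
  records <- list(); errors <- list()
  for (sz in names(subsets)) {
    res <- tryCatch({
      model <- train_segmenter_3d(cases[subsets[[sz]]], arch = tc$arch,
                                  cfg = tc$sampling, steps = tc$steps,
                                  lr = tc$lr, seed = seed)
      preds <- lapply(eval_cases, function(cs) {
        pm <- predict_3d_tiled(model$model, cs$volume)
        postprocess(pm)
      })
      evaluate_cases(preds, lapply(eval_cases, `[[`, "mask"))
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[sz]] <- conditionMessage(res)
    else records[[sz]] <- res
  }
  medians <- vapply(records, function(r) stats::median(r$dice), numeric(1))
  comparisons <- NULL
  szs <- names(records)
  if (length(szs) > 1) {
    comparisons <- do.call(rbind, lapply(seq_len(length(szs) - 1), function(i) {
      a <- records[[szs[i + 1]]]$dice
      b <- records[[szs[i]]]$dice
      if (length(a) < 5) {
        # too few paired cases for the signed-rank test
        w <- list(p = NA_real_, significant = NA)
      } else {
        w <- wilcoxon_compare(a, b, alpha = alpha)
      }
      data.frame(from = szs[i], to = szs[i + 1], p = w$p,
                 significant = w$significant, stringsAsFactors = FALSE)
    }))
  }
  list(records = records, medians = medians, comparisons = comparisons,
       errors = errors)
}
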