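# Training harnesses binding the two class-balancing strategies to the
# generic Adam loop. One case per minibatch keeps feature extents
# uniform; cases rotate across steps under the experiment seed.

mix_seed <- function(seed, step) {
  as.integer((as.numeric(seed) * 48271 + step * 16807) %% 2147483629)
}

#' Build training cases from a phantom cohort
#'
#' Networks segment the left gland only; right glands are converted to
#' additional left-sided cases by sagittal mirroring (data
#' augmentation), doubling the usable references.
#'
#' @param phantoms list of `phantom` objects.
#' @param augment_mirror include mirrored right-gland cases.
#' @return list of `list(volume, mask)` training cases.
#' @export
cohort_training_cases <- function(phantoms, augment_mirror = TRUE) {
  out <- list()
  for (ph in phantoms) {
    out[[length(out) + 1L]] <- list(volume = ph$volume, mask = ph$left)
    if (augment_mirror) {
      mr <- mirror_sagittal(ph$volume, ph$right)
      out[[length(out) + 1L]] <- list(volume = mr$volume, mask = mr$mask)
    }
  }
  out
}

#' Load training cases from a cohort manifest
#'
#' Reads the `manifest.csv` written by [generate_cohort()] (columns
#' `case_id, volume, mask_left, mask_right`) and returns in-memory
#' cases, mirroring right-gland references into left-sided ones.
#'
#' @param manifest data.frame or path to the CSV.
#' @param augment_mirror include mirrored right-gland cases.
#' @return list of `list(volume, mask)`.
#' @export
load_training_cases <- function(manifest, augment_mirror = TRUE) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    vol <- read_volume(manifest$volume[i])
    ml <- read_mask(manifest$mask_left[i], laterality = "left")
    out[[length(out) + 1L]] <- list(volume = vol, mask = ml)
    if (augment_mirror && "mask_right" %in% names(manifest)) {
      mr0 <- read_mask(manifest$mask_right[i], laterality = "right")
      mr <- mirror_sagittal(vol, mr0)
      out[[length(out) + 1L]] <- list(volume = mr$volume, mask = mr$mask)
    }
  }
  out
}

#' Train the 3-D patch-based segmenter
#'
#' Controlled batch composition: each minibatch is drawn from one
#' training case with [sample_balanced_patches()], so a fixed fraction
#' of patches overlaps the gland with their classified centre while the
#' rest sample background from the whole volume (this is what lets the
#' 3-D model suppress distant false positives).
#'
#' @param cases list of `list(volume, mask)`.
#' @param arch a 3-D [arch_spec()].
#' @param cfg a [sampling_config()]; `patch_extent` and `batch_size`
#'   control the minibatch.
#' @param steps,lr optimisation settings (Adam).
#' @param seed experiment seed (weights + sampling).
#' @param verbose see [train_unet()].
#' @return `list(model, loss)`.
#' @export
train_segmenter_3d <- function(cases, arch = arch_spec(3, base_channels = 4),
                               cfg = sampling_config(
                                 patch_extent = c(56L, 56L, 48L),
                                 batch_size = 4L),
                               steps = 200L, lr = 3e-3, seed = 1L,
                               verbose = 0L) {
  stopifnot(arch$dimensionality == 3L, length(cases) >= 1L)
  model <- build_unet(arch, seed = seed)
  n_fg <- as.integer(round(cfg$batch_size * cfg$fg_fraction))
  cfg_fg <- cfg; cfg_fg$batch_size <- 1L; cfg_fg$fg_fraction <- 1
  cfg_bg <- cfg; cfg_bg$batch_size <- 1L; cfg_bg$fg_fraction <- 0
  # mixed-case minibatches (one patch per drawn case) with the exact
  # foreground composition preserved; keeps batch-norm statistics
  # representative of unseen cases
  batch_fn <- function(step) {
    s <- mix_seed(seed, step)
    cis <- with_preserved_seed(s,
      sample.int(length(cases), cfg$batch_size, replace = TRUE))
    patches <- lapply(seq_along(cis), function(i) {
      cs <- cases[[cis[i]]]
      sample_balanced_patches(cs$volume, cs$mask,
                              if (i <= n_fg) cfg_fg else cfg_bg,
                              arch = arch, seed = mix_seed(s, i))[[1]]
    })
    list(x = lapply(patches, function(p)
           array(hu_normalize(p$x), dim = c(dim(p$x), 1L))),
         y = lapply(patches, `[[`, "y"))
  }
  train_unet(model, batch_fn, steps = steps, lr = lr, verbose = verbose)
}

#' Train a 2-D slice segmenter with the ROI strategy
#'
#' Slices are drawn only from the ROI around the gland
#' ([compute_roi()]), mirror-padded to a feasible valid-convolution
#' input extent; labels are mirror-padded consistently so the loss sees
#' the full classified region.
#'
#' @param cases list of `list(volume, mask)`.
#' @param arch a 2-D [arch_spec()].
#' @param cfg a [sampling_config()]; its `view` selects the slice
#'   orientation and `batch_size` the slices per step.
#' @param steps,lr,seed,verbose as in [train_segmenter_3d()].
#' @return `list(model, loss)`.
#' @export
train_segmenter_2d_roi <- function(cases,
                                   arch = arch_spec(2, base_channels = 8),
                                   cfg = sampling_config(view = "axial",
                                                         batch_size = 8L),
                                   steps = 200L, lr = 3e-3, seed = 1L,
                                   verbose = 0L) {
  stopifnot(arch$dimensionality == 2L, length(cases) >= 1L)
  model <- build_unet(arch, seed = seed)
  red2 <- valid_reduction(arch) %/% 2L
  # one slice per randomly drawn case: mixed-case minibatches keep the
  # batch-norm statistics representative of unseen cases (single-case
  # batches make the running averages match no case at inference)
  batch_fn <- function(step) {
    s <- mix_seed(seed, step)
    cis <- with_preserved_seed(s,
      sample.int(length(cases), cfg$batch_size, replace = TRUE))
    slices <- lapply(seq_along(cis), function(i) {
      cs <- cases[[cis[i]]]
      sample_roi_slices(cs$volume, cs$mask, cfg, n = 1L,
                        seed = mix_seed(s, i))[[1]]
    })
    xs <- vector("list", length(slices))
    ys <- vector("list", length(slices))
    for (i in seq_along(slices)) {
      img <- hu_normalize(slices[[i]]$image)
      n12 <- dim(img)
      Iext <- min_input_for_output(arch, n12)
      emb <- embed_mirror_2d(img, Iext)
      Oext <- valid_output_size(arch, Iext)
      xs[[i]] <- array(emb$m, dim = c(Iext, 1L, 1L))
      lab3 <- array(slices[[i]]$label, dim = c(n12, 1L))
      ys[[i]] <- extract_mirror(lab3, c(red2 - emb$off, 0L),
                                c(Oext, 1L))
    }
    list(x = xs, y = ys)
  }
  train_unet(model, batch_fn, steps = steps, lr = lr, verbose = verbose)
}

#' Crop a volume or mask to an ROI box
#'
#' @param obj a [volume_grid()] or [binary_mask()].
#' @param roi an `roi_box` from [compute_roi()].
#' @return the cropped object (origin shifted accordingly).
#' @export
crop_to_roi <- function(obj, roi) {
  stopifnot(inherits(roi, "roi_box"))
  v <- obj$voxels[(roi$lo[1] + 1L):roi$hi[1],
                  (roi$lo[2] + 1L):roi$hi[2],
                  (roi$lo[3] + 1L):roi$hi[3], drop = FALSE]
  origin <- obj$origin + roi$lo * obj$spacing
  if (inherits(obj, "volume_grid")) volume_grid(v, obj$spacing, origin)
  else if (inherits(obj, "binary_mask"))
    binary_mask(v, obj$spacing, origin, laterality = obj$laterality)
  else prob_map(v, obj$spacing, origin)
}
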