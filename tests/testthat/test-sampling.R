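# Class-balancing strategies: ROI computation, slice and patch sampling.

test_that("ROI follows the margin rules and clips to the volume", {
  # axial: foreground slices 40..49 (0-based), margin 5, 100 slices
  v <- array(FALSE, c(10, 10, 100))
  v[4:6, 4:6, 41:50] <- TRUE
  m <- binary_mask(v, c(1, 1, 2))
  roi <- compute_roi(m, sampling_config(view = "axial"))
  expect_identical(c(roi$lo[3], roi$hi[3]), c(35L, 55L))
  expect_identical(c(roi$lo[1], roi$hi[1]), c(0L, 10L))  # full extent

  # clipping at the volume edge
  v0 <- array(FALSE, c(10, 10, 20)); v0[4, 4, 1:3] <- TRUE
  roi0 <- compute_roi(binary_mask(v0, c(1, 1, 2)),
                      sampling_config(view = "axial"))
  expect_identical(c(roi0$lo[3], roi0$hi[3]), c(0L, 8L))

  # sagittal: view margin on x, 25-voxel restriction on z
  vs <- array(FALSE, c(40, 40, 200))
  vs[21:25, 15:20, 31:40] <- TRUE  # z 30..39 0-based
  rs <- compute_roi(binary_mask(vs, c(1, 1, 2)),
                    sampling_config(view = "sagittal"))
  expect_identical(c(rs$lo[3], rs$hi[3]), c(5L, 65L))
  expect_identical(c(rs$lo[1], rs$hi[1]), c(15L, 30L))
  expect_identical(c(rs$lo[2], rs$hi[2]), c(0L, 40L))

  expect_error(compute_roi(binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
                           sampling_config()), "empty mask")
})

test_that("ROI equals a brute-force slice scan on random masks", {
  set.seed(7)
  for (trial in 1:10) {
    ext <- sample(8:20, 3, replace = TRUE)
    v <- array(FALSE, ext)
    n <- sample(1:10, 1)
    v[cbind(sample(ext[1], n, TRUE), sample(ext[2], n, TRUE),
            sample(ext[3], n, TRUE))] <- TRUE
    m <- binary_mask(v, c(1, 1, 1))
    for (view in c("axial", "coronal", "sagittal")) {
      cfg <- sampling_config(view = view, slice_margin = 2L,
                             transverse_margin = 3L)
      roi <- compute_roi(m, cfg)
      va <- switch(view, sagittal = 1L, coronal = 2L, axial = 3L)
      has_fg <- vapply(seq_len(ext[va]), function(k) {
        any(switch(va, v[k, , ], v[, k, ], v[, , k]))
      }, logical(1))
      expect_identical(roi$lo[va],
                       max(0L, min(which(has_fg)) - 1L - 2L))
      expect_identical(roi$hi[va],
                       min(ext[va], max(which(has_fg)) + 2L))
    }
  }
})

test_that("slice sampling is uniform within the ROI and seeded", {
  ph <- small_phantom(1)
  cfg <- sampling_config(view = "axial", batch_size = 4L, rng_seed = 3L)
  roi <- compute_roi(ph$left, cfg)
  sl <- sample_roi_slices(ph$volume, ph$left, cfg, n = 1000)
  ks <- vapply(sl, `[[`, integer(1), "index")
  expect_true(all(ks >= roi$lo[3] & ks < roi$hi[3]))
  # determinism
  sl2 <- sample_roi_slices(ph$volume, ph$left, cfg, n = 1000)
  expect_identical(ks, vapply(sl2, `[[`, integer(1), "index"))
  # uniformity over 10,000 draws (chi-square at 0.01)
  ks10 <- vapply(sample_roi_slices(ph$volume, ph$left, cfg, n = 10000),
                 `[[`, integer(1), "index")
  counts <- table(factor(ks10, levels = roi$lo[3]:(roi$hi[3] - 1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # image/label slices align with the volume
  k <- sl[[1]]$index
  expect_identical(dim(sl[[1]]$image), dim(ph$volume$voxels)[1:2])
  expect_equal(sl[[1]]$label, ph$left$voxels[, , k + 1] * 1,
               ignore_attr = TRUE)
})

test_that("balanced batches contain exactly the configured foreground count", {
  ph <- small_phantom(1)
  arch <- arch_spec(3)
  ps <- patch_spec(c(56L, 56L, 48L), arch)
  cfg <- sampling_config(patch_extent = c(56L, 56L, 48L), batch_size = 6L,
                         fg_fraction = 0.5)
  for (s in 1:10) {
    b <- sample_balanced_patches(ph$volume, ph$left, cfg, arch, seed = s)
    overlap <- vapply(b, function(p) sum(p$y) > 0, logical(1))
    expect_identical(sum(overlap[vapply(b, `[[`, logical(1), "fg")]), 3L)
    expect_identical(sum(vapply(b, `[[`, logical(1), "fg")), 3L)
    expect_true(all(vapply(b, function(p)
      identical(dim(p$x), ps$input_extent), logical(1))))
    expect_true(all(vapply(b, function(p)
      identical(dim(p$y), ps$output_extent), logical(1))))
    # input patch is the context around the labelled centre
    p1 <- b[[1]]
    inside <- all(p1$start >= 0L) &&
      all(p1$start + ps$output_extent <= dim(ph$volume$voxels))
    if (inside) {
      ctr <- p1$x[20 + seq_len(16), 20 + seq_len(16), 20 + seq_len(8)]
      expect_equal(ctr,
                   ph$volume$voxels[p1$start[1] + seq_len(16),
                                    p1$start[2] + seq_len(16),
                                    p1$start[3] + seq_len(8)],
                   ignore_attr = TRUE)
    }
  }
  # fg_fraction 0: plain uniform sampling, no constraint, works without fg
  empty <- binary_mask(array(FALSE, dim(ph$volume$voxels)), ph$volume)
  cfg0 <- sampling_config(patch_extent = c(56L, 56L, 48L), batch_size = 4L,
                          fg_fraction = 0)
  b0 <- sample_balanced_patches(ph$volume, empty, cfg0, arch)
  expect_length(b0, 4L)
  expect_error(sample_balanced_patches(ph$volume, empty,
                                       sampling_config(
                                         patch_extent = c(56L, 56L, 48L),
                                         batch_size = 4L), arch),
               "no foreground")
})

test_that("foreground patch centres stay near the mask (geometric necessity)", {
  # 40^3 toy with a compact blob
  v <- array(FALSE, c(40, 40, 40)); v[18:23, 17:22, 19:24] <- TRUE
  vol <- volume_grid(array(0, c(40, 40, 40)), c(1, 1, 1))
  m <- binary_mask(v, vol)
  arch <- arch_spec(3)
  cfg <- sampling_config(patch_extent = c(44L, 44L, 44L), batch_size = 8L,
                         fg_fraction = 1)
  oe <- patch_spec(c(44L, 44L, 44L), arch)$output_extent  # 4x4x4
  bb <- apply(which(v, arr.ind = TRUE), 2, range)
  for (s in 1:5) {
    b <- sample_balanced_patches(vol, m, cfg, arch, seed = s)
    for (p in b) {
      expect_gt(sum(p$y), 0)
      centre <- p$start + oe / 2  # 0-based centre of the label region
      expect_true(all(centre + 1 >= bb[1, ] - oe / 2) &&
                  all(centre + 1 <= bb[2, ] + oe / 2))
    }
  }
})

test_that("training subsets are nested, seeded and size-faithful", {
  ids <- sprintf("c%03d", 1:467)
  s <- select_training_subsets(ids, c(50, 150, 250, 350, 450), seed = 4)
  expect_identical(vapply(s, length, integer(1)),
                   c(`50` = 50L, `150` = 150L, `250` = 250L, `350` = 350L,
                     `450` = 450L))
  for (i in 1:4) expect_true(all(s[[i]] %in% s[[i + 1]]))
  expect_identical(s, select_training_subsets(ids, c(50, 150, 250, 350, 450),
                                              seed = 4))
  expect_false(identical(s[[1]],
                         select_training_subsets(ids, 50, seed = 5)[[1]]))
  s2 <- select_training_subsets(letters[1:6], c(2, 4), seed = 1)
  expect_true(all(s2[[1]] %in% s2[[2]]))
  expect_error(select_training_subsets(letters[1:3], 4), "exceeds")
})
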