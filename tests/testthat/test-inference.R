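# Full-volume inference, ensembling and postprocessing.

test_that("majority vote equals the per-voxel count oracle", {
  set.seed(11)
  sp <- c(1, 1, 2)
  ms <- lapply(1:3, function(i)
    binary_mask(array(runif(125) < 0.5, c(5, 5, 5)), sp))
  fused <- ensemble_vote(ms)
  counts <- ms[[1]]$voxels + ms[[2]]$voxels + ms[[3]]$voxels
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_identical(fused$voxels[i, j, k], counts[i, j, k] >= 2)
  # trivial cases
  expect_identical(ensemble_vote(list(ms[[1]], ms[[1]], ms[[1]]))$voxels,
                   ms[[1]]$voxels)
  em <- binary_mask(array(FALSE, c(5, 5, 5)), sp)
  expect_identical(ensemble_vote(list(em, ms[[2]], ms[[2]]))$voxels,
                   ms[[2]]$voxels)
  # permutation invariance and monotonicity
  expect_identical(ensemble_vote(ms[c(3, 1, 2)])$voxels, fused$voxels)
  grown <- ms
  grown[[1]]$voxels[1, 1, 1] <- TRUE
  expect_true(all(ensemble_vote(grown)$voxels >= fused$voxels))
  bad <- binary_mask(array(FALSE, c(4, 5, 5)), sp)
  expect_error(ensemble_vote(list(ms[[1]], ms[[2]], bad)), "identical grids")
})

test_that("postprocess keeps one largest component and flags empty results", {
  v <- array(0, c(20, 10, 6))
  v[2:6, 2:5, 2:6] <- 0.9        # 100 voxels
  v[15:16, 7:9, 2:3] <- 0.8      # 12 voxels
  pm <- prob_map(v, c(1, 1, 2))
  out <- postprocess(pm)
  expect_false(attr(out, "empty_result"))
  expect_identical(sum(out$voxels), 100L)
  expect_false(any(out$voxels[15:16, 7:9, 2:3]))
  lab <- table(out$voxels)
  # exactly one component survives
  expect_true(all(which(out$voxels, arr.ind = TRUE)[, 1] <= 6))

  # all below threshold: empty mask, flagged, no error
  out0 <- postprocess(prob_map(array(0.4, c(4, 4, 4)), c(1, 1, 1)))
  expect_true(attr(out0, "empty_result"))
  expect_false(any(out0$voxels))

  # threshold is inclusive (p >= 0.5 is foreground)
  out5 <- postprocess(prob_map(array(0.5, c(2, 2, 2)), c(1, 1, 1)))
  expect_true(all(out5$voxels))

  # equal-size tie: the component containing the lowest linear index wins,
  # deterministically across runs
  vt <- array(0, c(10, 4, 4))
  vt[2:3, 2:3, 2:3] <- 1   # 8 voxels, lower linear indices
  vt[7:8, 2:3, 2:3] <- 1   # 8 voxels
  r1 <- postprocess(prob_map(vt, c(1, 1, 1)))
  r2 <- postprocess(prob_map(vt, c(1, 1, 1)))
  expect_identical(r1$voxels, r2$voxels)
  expect_true(any(r1$voxels[2:3, , ]))
  expect_false(any(r1$voxels[7:8, , ]))

  # resampling to the original grid by nearest neighbour
  out_rs <- postprocess(pm, original_grid = list(
    extent = c(20L, 10L, 12L), spacing = c(1, 1, 1), origin = c(0, 0, 0)))
  expect_identical(dim(out_rs$voxels), c(20L, 10L, 12L))
})

test_that("tiled 3-D inference equals the whole-volume pass", {
  ph <- small_phantom(5)
  model <- memo("untrained3", function()
    build_unet(arch_spec(3, base_channels = 2), seed = 13))
  t1 <- predict_3d_tiled(model, ph$volume,
                         patch_spec(c(52L, 52L, 48L), model$spec))
  whole <- predict_3d_whole(model, ph$volume)
  expect_identical(dim(t1$voxels), dim(ph$volume$voxels))
  expect_lt(max(abs(t1$voxels - whole$voxels)), 1e-10)
  # a volume equal to one output block is a single tile == direct pass
  sub <- volume_grid(ph$volume$voxels[1:32, 1:32, 1:16], ph$volume$spacing)
  t2 <- predict_3d_tiled(model, sub, patch_spec(arch = model$spec))
  w2 <- predict_3d_whole(model, sub)
  expect_lt(max(abs(t2$voxels - w2$voxels)), 1e-10)
})

test_that("2-D per-slice prediction aligns with the volume and tiles exactly", {
  ph <- small_phantom(5)
  model2 <- memo("untrained2", function()
    build_unet(arch_spec(2, base_channels = 2), seed = 17))
  for (view in c("axial", "coronal", "sagittal")) {
    pm <- predict_2d(model2, ph$volume, view)
    expect_identical(dim(pm$voxels), dim(ph$volume$voxels))
    expect_true(all(pm$voxels >= 0 & pm$voxels <= 1))
  }
  # stitched tiles equal the single-pass slice prediction
  pm_one <- predict_2d(model2, ph$volume, "axial")
  pm_tiled <- predict_2d(model2, ph$volume, "axial", tile_extent = 24)
  expect_lt(max(abs(pm_one$voxels - pm_tiled$voxels)), 1e-10)
})

test_that("x-symmetric weights give mirror-equivariant 2-D predictions", {
  model2 <- build_unet(arch_spec(2, base_channels = 2), seed = 19)
  # symmetrise every kernel along x so the network commutes with the flip
  for (nm in grep("_w$", names(model2$params), value = TRUE)) {
    w <- model2$params[[nm]]
    model2$params[[nm]] <- (w + w[rev(seq_len(dim(w)[1])), , , , ,
                                  drop = FALSE]) / 2
  }
  ph <- small_phantom(5)
  p_orig <- predict_2d(model2, ph$volume, "axial")
  mv <- mirror_sagittal(ph$volume)
  p_mirr <- predict_2d(model2, mv, "axial")
  back <- p_mirr$voxels[rev(seq_len(dim(p_mirr$voxels)[1])), , ]
  expect_lt(max(abs(back - p_orig$voxels)), 1e-8)
})
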