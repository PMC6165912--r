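# Volume I/O, resampling, couch removal and mirroring.

test_that("volumes round-trip through NIfTI and MetaImage", {
  ph <- small_phantom(1)
  for (ext in c(".nii", ".nii.gz", ".mha", ".mhd")) {
    path <- tempfile(fileext = ext)
    write_volume(ph$volume, path)
    v2 <- read_volume(path)
    expect_identical(dim(v2$voxels), dim(ph$volume$voxels))
    expect_lt(max(abs(v2$spacing - ph$volume$spacing)), 1e-6)
    # float32 storage: ~1e-4 HU quantisation
    expect_lt(max(abs(v2$voxels - ph$volume$voxels)), 1e-3)
    m <- tempfile(fileext = ext)
    write_mask(ph$left, m)
    m2 <- read_mask(m, laterality = "left")
    expect_identical(m2$voxels, ph$left$voxels)
    expect_identical(m2$laterality, "left")
  }
})

test_that("header spacing is honoured and malformed files are refused", {
  v <- volume_grid(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1.0, 1.0, 3.0),
                   origin = c(-2, 0, 10.5))
  path <- tempfile(fileext = ".nii")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$spacing, c(1.0, 1.0, 3.0), tolerance = 1e-6)
  expect_equal(v2$origin, c(-2, 0, 10.5), tolerance = 1e-5)

  # a 4-D file must be rejected: patch dim[0]/dim[4] in a valid header
  raw4 <- readBin(path, "raw", file.info(path)$size)
  raw4[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")[1:2]
  raw4[49:50] <- writeBin(2L, raw(), size = 2, endian = "little")[1:2]
  p4 <- tempfile(fileext = ".nii")
  writeBin(raw4, p4)
  expect_error(read_volume(p4), "3-D")

  expect_error(read_volume(tempfile(fileext = ".nii")), "no such file")
  junk <- tempfile(fileext = ".nii")
  writeBin(raw(100), junk)
  expect_error(read_volume(junk), "NIfTI")
  txt <- tempfile(fileext = ".txt")
  writeLines("not a volume", txt)
  expect_error(read_volume(txt), "unsupported")
})

test_that("transverse resampling follows the origin-anchored grid rule", {
  # identity path
  v <- volume_grid(array(rnorm(4 * 4 * 9), c(4, 4, 9)), c(1, 1, 2))
  expect_identical(resample_transverse(v, 2.0), v)
  # constant preservation (kernel renormalisation)
  vc <- volume_grid(array(7.5, c(4, 4, 31)), c(1, 1, 3))
  r <- resample_transverse(vc, 2.0)
  expect_lt(max(abs(r$voxels - 7.5)), 1e-6)
  # 31 slices at 3 mm = 90 mm extent -> floor(90/2) + 1 = 46 slices,
  # cross-checked against an independent physical-extent computation
  n_expected <- floor((31 - 1) * 3.0 / 2.0) + 1
  expect_identical(dim(r$voxels)[3], as.integer(n_expected))
  expect_identical(dim(r$voxels)[3], 46L)
  expect_identical(dim(r$voxels)[1:2], c(4L, 4L))
  expect_equal(r$spacing, c(1, 1, 2))
  # physical z-extent changes by less than one target spacing
  expect_lt(abs((dim(r$voxels)[3] - 1) * 2.0 - 90), 2.0)
  # a smooth profile is interpolated accurately away from edges
  z <- (0:30) * 3
  vs <- volume_grid(array(rep(sin(z / 15), each = 16), c(4, 4, 31)),
                    c(1, 1, 3))
  rs <- resample_transverse(vs, 2.0)
  zt <- (0:45) * 2
  inner <- zt > 9 & zt < 81
  expect_lt(max(abs(rs$voxels[1, 1, inner] - sin(zt[inner] / 15))), 0.01)
  expect_error(resample_transverse(volume_grid(array(1, c(2, 2, 1)),
                                               c(1, 1, 3)), 2.0),
               "single-slice")
})

test_that("mask resampling equals the exhaustive nearest-centre oracle", {
  set.seed(42)
  for (trial in 1:8) {
    src_ext <- sample(3:8, 3, replace = TRUE)
    src_sp <- runif(3, 0.5, 3)
    tgt_ext <- sample(3:10, 3, replace = TRUE)
    tgt_sp <- runif(3, 0.5, 3)
    org_s <- runif(3, -2, 2); org_t <- org_s + runif(3, -1, 1)
    m <- binary_mask(array(runif(prod(src_ext)) < 0.4, src_ext), src_sp,
                     org_s)
    out <- resample_mask_to_grid(
      m, list(extent = tgt_ext, spacing = tgt_sp, origin = org_t))
    # oracle: per target voxel, full search over source voxel centres
    for (i in seq_len(tgt_ext[1])) for (j in seq_len(tgt_ext[2]))
      for (k in seq_len(tgt_ext[3])) {
        p <- org_t + (c(i, j, k) - 1) * tgt_sp
        best <- c(1L, 1L, 1L)
        for (ax in 1:3) {
          cand <- org_s[ax] + (seq_len(src_ext[ax]) - 1) * src_sp[ax]
          dists <- abs(cand - p[ax])
          best[ax] <- which(dists <= min(dists) + 1e-12)[1]  # tie: lower
        }
        expect_identical(out$voxels[i, j, k],
                         m$voxels[best[1], best[2], best[3]])
      }
  }
  # identity and empty-mask invariants
  ph <- small_phantom(1)
  self <- resample_mask_to_grid(ph$left, ph$volume)
  expect_identical(self$voxels, ph$left$voxels)
  em <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 2))
  out <- resample_mask_to_grid(em, list(extent = c(5, 5, 5),
                                        spacing = c(1, 1, 1),
                                        origin = c(0, 0, 0)))
  expect_false(any(out$voxels))
})

test_that("couch removal masks the patient and excludes the couch slab", {
  ph <- memo("ph_couch", function()
    generate_phantom(small_phantom_config(seed = 8, couch = TRUE)))
  body <- remove_couch(ph$volume)
  expect_false(any(body$voxels & ph$meta$couch))
  expect_gt(mean(body$voxels[ph$meta$body]), 0.999)
  # without couch: mask equals the thresholded body up to hole filling
  ph2 <- small_phantom(9)
  b2 <- remove_couch(ph2$volume)
  expect_gte(sum(b2$voxels & ph2$meta$body) / sum(ph2$meta$body), 0.999)
  expect_lt(mean(b2$voxels[!ph2$meta$body]), 0.01)
  # applying the mask blanks the couch to air
  blanked <- apply_body_mask(ph$volume, body)
  expect_true(all(blanked$voxels[ph$meta$couch] == -1024))
  expect_error(remove_couch(volume_grid(array(-1024, c(4, 4, 4)),
                                        c(1, 1, 1))), "no body")
})

test_that("sagittal mirroring is an involution with exact index arithmetic", {
  ph <- small_phantom(1)
  mm <- mirror_sagittal(ph$volume, ph$right)
  back <- mirror_sagittal(mm$volume, mm$mask)
  expect_identical(back$volume$voxels, ph$volume$voxels)
  expect_identical(back$mask$voxels, ph$right$voxels)
  expect_identical(mm$mask$laterality, "left")
  expect_identical(back$mask$laterality, "right")
  # index arithmetic on a 5x5x5 toy: foreground at x-index k maps to Nx-1-k
  for (k in 0:4) {
    v <- array(FALSE, c(5, 5, 5)); v[k + 1, 2, 3] <- TRUE
    toy <- binary_mask(v, c(1, 1, 1), laterality = "right")
    vol <- volume_grid(array(0, c(5, 5, 5)), c(1, 1, 1))
    flipped <- mirror_sagittal(vol, toy)$mask
    expect_identical(unname(which(flipped$voxels, arr.ind = TRUE)[1, ]),
                     c(5L - k, 2L, 3L))
  }
  # volume and mask stay consistent under joint mirroring
  expect_equal(dice(mm$mask, binary_mask(
    ph$right$voxels[rev(seq_len(64)), , ], ph$volume)), 1)
})
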