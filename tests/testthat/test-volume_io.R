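test_that("NIfTI round-trip preserves voxels, labels and spacing", {
  v <- ct_volume(array(stats::rnorm(8^3, -800, 120), c(8, 8, 8)),
                 spacing = c(2, 2, 2.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-12)
  expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)

  labs <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
  pm <- prm_map(labs, source = "ground-truth", spacing = c(1, 1, 1))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(pm, f2)
  back <- read_volume(f2, clamp = FALSE)
  expect_identical(array(as.integer(back$voxels), dim(labs)), pm$labels)
})

test_that("volume ingest enforces the CT value contract", {
  ## clamp to the 12-bit HU range
  a <- array(-1000, c(4, 4, 4)); a[1, 1, 1] <- -2000; a[2, 2, 2] <- 5000
  v <- ct_volume(a)
  expect_equal(v$voxels[1, 1, 1], -1024)
  expect_equal(v$voxels[2, 2, 2], 3071)
  ## a clamped file reads back clamped
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), f)
  expect_equal(read_volume(f)$voxels[1, 1, 1], -1024)
  ## distinct errors
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2)),
                                     datatype = "double"), f4)
  expect_error(read_volume(f4), "expected 3D")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(ct_volume(array(0, c(2, 2))), "expected 3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(write_volume(ct_volume(array(0, c(2, 2, 2))),
                            file.path(tempdir(), "nope", "x.nii.gz")),
               "directory")
})

test_that("threshold lung mask recovers the phantom lungs", {
  ph <- cached_phantom("io32", small_spec(seed = 4))
  m <- threshold_lung_mask(ph$insp)
  cov <- sum(m$voxels & ph$mask$voxels) / sum(ph$mask$voxels)
  expect_gt(cov, 0.99)
  ## no spill into soft tissue beyond the construction lung
  expect_lt(sum(m$voxels & !ph$mask$voxels) / sum(ph$mask$voxels), 0.02)
  ## uniform soft tissue has no lung
  expect_error(threshold_lung_mask(ct_volume(array(40, c(16, 16, 16)))),
               "no lung found")
  ## invariant to a +5 HU bias applied to soft tissue only
  biased <- ph$insp
  body <- biased$voxels > -320
  biased$voxels[body] <- biased$voxels[body] + 5
  m2 <- threshold_lung_mask(biased)
  expect_identical(m2$voxels, m$voxels)
  ## deterministic
  expect_identical(threshold_lung_mask(ph$insp)$voxels, m$voxels)
})

test_that("PRM overlay renders one pixel per labelled voxel in class colors", {
  labs <- array(0L, c(5, 5, 3))
  labs[2, 2, 2] <- 1L  # normal, green
  labs[3, 3, 2] <- 2L  # fSAD, yellow
  labs[4, 4, 2] <- 3L  # emphysema, red
  pm <- prm_map(labs)
  dir <- tempfile()
  files <- write_prm_overlay(pm, dir)
  expect_length(files, 3)
  img <- png::readPNG(files[2])
  greens <- sum(img[, , 1] == 0 & img[, , 2] == 1 & img[, , 3] == 0 &
                  img[, , 4] == 1)
  yellows <- sum(img[, , 1] == 1 & img[, , 2] == 1 & img[, , 3] == 0 &
                   img[, , 4] == 1)
  reds <- sum(img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0 &
                img[, , 4] == 1)
  expect_equal(c(greens, yellows, reds), c(1, 1, 1))
  ## blank slice: fully transparent
  img1 <- png::readPNG(files[1])
  expect_true(all(img1[, , 4] == 0))
  ## pixel count per color equals label count per class on a random map
  labs2 <- array(sample(0:3, 6 * 6 * 2, replace = TRUE), c(6, 6, 2))
  d2 <- tempfile()
  f2 <- write_prm_overlay(prm_map(labs2), d2)
  counts <- c(0, 0, 0)
  for (f in f2) {
    im <- png::readPNG(f)
    counts <- counts + c(
      sum(im[, , 1] == 0 & im[, , 2] == 1 & im[, , 4] == 1),
      sum(im[, , 1] == 1 & im[, , 2] == 1 & im[, , 3] == 0 & im[, , 4] == 1),
      sum(im[, , 1] == 1 & im[, , 2] == 0 & im[, , 4] == 1))
  }
  expect_equal(counts, as.numeric(table(factor(labs2, levels = 0:3))[2:4]))
})
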