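test_that("lesion sampling hits the target class fractions", {
  spec <- phantom_spec(target_fsad_fraction = 20, target_emph_fraction = 5,
                       seed = 7)
  set.seed(7)
  tissue <- sample_lesion_field(spec)
  lung <- tissue > 0L
  f_fsad <- 100 * sum(tissue == 2L) / sum(lung)
  f_emph <- 100 * sum(tissue == 3L) / sum(lung)
  expect_gte(f_fsad, 17); expect_lte(f_fsad, 23)
  expect_gte(f_emph, 2); expect_lte(f_emph, 8)
  ## zero targets give an all-normal lung
  spec0 <- small_spec(seed = 7, target_fsad_fraction = 0,
                      target_emph_fraction = 0)
  set.seed(7)
  t0 <- sample_lesion_field(spec0)
  expect_true(all(t0[t0 > 0L] == 1L))
  ## deterministic under a fixed seed
  set.seed(7); a <- sample_lesion_field(spec0)
  set.seed(7); b <- sample_lesion_field(spec0)
  expect_identical(a, b)
})

test_that("realized fractions track targets across seeds", {
  for (sd in 1:8) {
    ph <- generate_phantom(small_spec(seed = sd))
    fr <- prm_fractions(ph$truth)
    expect_lte(abs(fr$pct_fsad - 20), 3)
    expect_lte(abs(fr$pct_emph - 5), 3)
  }
})

test_that("phantom generation is deterministic and seed-sensitive", {
  a <- generate_phantom(small_spec(seed = 1))
  b <- generate_phantom(small_spec(seed = 1))
  expect_identical(a$insp$voxels, b$insp$voxels)
  expect_identical(a$exp$voxels, b$exp$voxels)
  expect_identical(a$truth$labels, b$truth$labels)
  c <- generate_phantom(small_spec(seed = 2))
  expect_false(identical(a$truth$labels, c$truth$labels))
})

test_that("identity expiration (no compression, no perturbation) only shifts density", {
  spec <- small_spec(seed = 3, compression = 1, perturb_amp = 0,
                     noise_sd = 0)
  ph <- generate_phantom(spec)
  expect_true(all(ph$field$displacement == 0))
  ## expiratory equals the density-shifted inspiratory voxel for voxel
  shift <- ph$exp$voxels - ph$insp$voxels
  expect_equal(unique(shift[ph$truth$labels == 1L]), 180)   # -880 -> -700
  expect_equal(unique(shift[ph$truth$labels == 2L]), -20)   # -880 -> -900
  expect_equal(unique(shift[ph$truth$labels == 3L]), 10)    # -975 -> -965
})

test_that("noiseless attenuation obeys the PRM rule by construction", {
  ph <- generate_phantom(small_spec(seed = 5, noise_sd = 0))
  exp_reg <- warp_volume(ph$exp, ph$field)
  fs <- ph$truth$labels == 2L
  em <- ph$truth$labels == 3L
  expect_true(all(ph$insp$voxels[fs] > -950))
  expect_true(all(exp_reg$voxels[fs] < -856))
  expect_true(all(ph$insp$voxels[em] < -950))
  expect_true(all(exp_reg$voxels[em] < -856))
})

test_that("ground-truth PRM recomputed through the classifier matches construction", {
  ph <- generate_phantom(small_spec(seed = 6, noise_sd = 0))
  res <- classify_prm(ph$insp, warp_volume(ph$exp, ph$field), ph$mask)
  m <- ph$mask$voxels
  expect_identical(res$map$labels[m], ph$truth$labels[m])
  ## with the default 10 HU noise the agreement stays near-perfect
  ph2 <- generate_phantom(small_spec(seed = 6))
  res2 <- classify_prm(ph2$insp, warp_volume(ph2$exp, ph2$field), ph2$mask)
  for (l in 1:3) expect_gte(dice(ph2$truth, res2$map, l), 0.95)
})

test_that("a deformation that would push the lung off-grid errors", {
  expect_error(generate_phantom(small_spec(seed = 1, compression = 0.2)),
               "outside the grid")
})
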