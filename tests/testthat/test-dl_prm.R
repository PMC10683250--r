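tiny_cfg <- function(...) {
  net_config(unet_depth = 2, base_channels = 2, patch_size = 16,
             lr = 1e-3, ...)
}

test_that("adversarial and L1 losses have their analytic values", {
  real <- array(-700, c(4, 4, 4))
  fake <- real
  ls <- gan_losses(real, fake, d_real = rep(1, 8), d_fake = rep(1, 8),
                   adv_type = "least-squares")
  expect_equal(ls$l1, 0)
  expect_equal(ls$adv_G, 0)  # D outputs the real label on fakes
  ce <- gan_losses(real, fake + 5, d_real = rep(0.5, 8),
                   d_fake = rep(0.5, 8), adv_type = "cross-entropy")
  expect_equal(ce$adv_G, log(2), tolerance = 1e-9)
  expect_equal(ce$adv_D, log(2), tolerance = 1e-9)
  expect_equal(ce$l1, 5)
})

test_that("soft thresholding relaxes the hard PRM rule", {
  p <- soft_threshold_prm(-900, -900, t = -856, tau = 0.01)
  expect_equal(unname(which.max(p[1, ])), 2L)  # fSAD
  ## probabilities sum to one voxel-wise
  set.seed(4)
  iv <- stats::rnorm(500, -900, 60); ev <- stats::rnorm(500, -850, 60)
  p <- soft_threshold_prm(iv, ev, t = -856, tau = 20)
  expect_equal(rowSums(p), rep(1, 500), tolerance = 1e-12)
  ## tau -> 0 argmax equals the hard rule on the exhaustive HU grid
  g <- hu_grid_pair()
  ## offset by 0.5 HU so no value sits exactly on a cut (the sigmoid
  ## relaxation is 1/2 there; the hard rule's boundary convention is
  ## checked separately in the prm_core tests)
  iv <- g$insp + 0.5; ev <- g$exp + 0.5
  p <- soft_threshold_prm(iv, ev, t = -856, tau = 1e-3)
  hard <- mapply(function(i, e) oracle_prm_voxel(i, e, TRUE), iv, ev)
  expect_identical(unname(apply(p, 1, which.max)), as.integer(hard))
  expect_error(soft_threshold_prm(-900, -900, -856, tau = 0), "tau")
})

test_that("consistency loss is a cross-entropy with the expected values", {
  onehot <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  expect_lte(consistency_loss(onehot, onehot), 1e-6)
  unif <- matrix(1 / 3, 4, 3)
  tgt <- matrix(c(0.2, 0.5, 0.3), 4, 3, byrow = TRUE)
  expect_equal(consistency_loss(unif, tgt), log(3), tolerance = 1e-9)
  ## decreases monotonically as seg moves toward the target
  prev <- Inf
  for (a in seq(0, 1, by = 0.25)) {
    seg <- (1 - a) * unif + a * tgt
    val <- consistency_loss(seg, tgt)
    expect_lte(val, prev + 1e-12)
    prev <- val
  }
  expect_error(consistency_loss(matrix(c(0.9, 0.9, 0.9), 1), tgt[1, , drop = FALSE]),
               "sum to 1")
})

test_that("residual application is additive and clamped", {
  g <- array(-700, c(3, 3, 3))
  expect_identical(apply_residual(g, array(0, c(3, 3, 3))), g)
  real <- array(stats::rnorm(27, -750, 40), c(3, 3, 3))
  expect_equal(apply_residual(g, real - g), real, tolerance = 1e-12)
  out <- apply_residual(g, array(-9000, c(3, 3, 3)))
  expect_true(all(out >= -1024 & out <= 3071))
})

test_that("fusion averages probabilities with deterministic tie-breaks", {
  d <- c(2, 2, 1)
  thr <- prm_map(array(c(2L, 2L, 1L, 0L), d), source = "threshold-derived")
  ## agreeing sources reproduce themselves
  seg <- matrix(0, 4, 3); seg[1, 2] <- 1; seg[2, 2] <- 1; seg[3, 1] <- 1
  seg[4, ] <- 1 / 3
  fused <- fuse_prm(seg, thr)
  expect_equal(as.integer(fused$labels), c(2L, 2L, 1L, 0L))
  ## uniform seg: the one-hot dominates
  unif <- matrix(1 / 3, 4, 3)
  expect_equal(as.integer(fuse_prm(unif, thr)$labels)[1], 2L)
  ## exact tie resolves by priority normal > fSAD > emphysema
  seg_tie <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  f2 <- fuse_prm(seg_tie, thr)     # avg = (0.5, 0.5, 0) at fSAD voxels
  expect_equal(as.integer(f2$labels)[1], 1L)
})

test_that("training loops run, record finite losses, and are seed-deterministic", {
  samples <- lapply(1:2, function(i)
    generate_phantom(small_spec(seed = i)))
  cfg <- tiny_cfg()
  ck <- train_expiratory_generator(samples, cfg, seed = 3, epochs = 1)
  expect_true(all(is.finite(unlist(ck$history))))
  expect_named(ck$history,
               c("epoch", "adv_D", "adv_G1", "adv_G2", "l1_g1_hu", "l1_g2_hu"))
  ck2 <- train_expiratory_generator(samples, cfg, seed = 3, epochs = 1)
  expect_identical(ck$history, ck2$history)
  pk <- train_prm_generator(samples, ck, cfg, seed = 3, epochs = 1)
  expect_true(all(is.finite(unlist(pk$history))))
  pk2 <- train_prm_generator(samples, ck, cfg, seed = 3, epochs = 1)
  expect_identical(pk$history, pk2$history)
  ## ablation configs drop their modules
  cfg_noref <- tiny_cfg(use_refiner = FALSE)
  ck3 <- train_expiratory_generator(samples, cfg_noref, seed = 3, epochs = 1)
  expect_true(all(ck3$history$adv_G2 == 0))
  cfg_seg <- tiny_cfg(use_threshold_head = FALSE, use_fusion = FALSE,
                      input_mode = "real_exp")
  pk3 <- train_prm_generator(samples, NULL, cfg_seg, seed = 3, epochs = 1)
  expect_true(all(pk3$history$cons == 0))
  expect_equal(pk3$threshold, -856)

  ## single-tile prediction equals one forward pass; mask zeroes outside
  s <- samples[[1]]
  sub <- ct_volume(s$insp$voxels[1:16, 1:16, 1:16],
                   spacing = s$insp$spacing)
  mvox <- s$mask$voxels[1:16, 1:16, 1:16]
  if (!any(mvox)) mvox[8, 8, 8] <- TRUE
  subm <- lung_mask(mvox)
  pr <- predict_prm(sub, subm, ck, pk)
  X <- matrix(lungprm:::.to_net(sub$voxels), ncol = 1)
  E <- lungprm:::.gen_exp_patch(ck, X, rep(16L, 3))
  expect_equal(as.numeric(pr$gen_exp$voxels),
               as.numeric(lungprm:::.from_net(E)), tolerance = 1e-9)
  expect_true(all(pr$pred$labels[!subm$voxels] == 0L))
})
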