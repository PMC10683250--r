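## Inspiratory-only PRM prediction: a cascaded expiratory generator
## (coarse UNet generator + conditional refiner sharing one patch
## discriminator) and a PRM generator (UNet segmenter with an HU residual
## head and a learnable expiratory-threshold MLP).  Networks operate on
## standardized intensities (HU + 800) / 200, centred near parenchymal
## attenuation so the class-discriminative contrast is order one.

.HU_SCALE <- 200   # HU per normalized network unit
.HU_SHIFT <- -800   # HU mapped to network zero

## Network intensity units: centred near parenchymal attenuation so the
## class-discriminative signal is O(1).
.to_net <- function(hu) (hu - .HU_SHIFT) / .HU_SCALE
.from_net <- function(x) x * .HU_SCALE + .HU_SHIFT

#' Network and training configuration
#'
#' @param unet_depth number of UNet resolution levels (>= 2).
#' @param base_channels channels at the finest level; doubled per level.
#' @param patch_size cubic training patch edge, voxels; must be divisible
#'   by `2^(unet_depth - 1)`.
#' @param use_refiner include the conditional refiner generator (cascade).
#' @param use_threshold_head include the learnable expiratory-threshold
#'   MLP on the PRM generator.
#' @param use_fusion fuse the segmentation PRM with the threshold PRM at
#'   inference.
#' @param adv_type adversarial loss: `"least-squares"` or
#'   `"cross-entropy"`.
#' @param lambda_l1 weight of the L1 reconstruction term of each
#'   generator.
#' @param lambda_consistency weight of the segmentation/threshold
#'   consistency loss.
#' @param lambda_residual weight of the HU-residual supervision.
#' @param soft_tau temperature of the differentiable threshold, HU.
#' @param insp_cut fixed inspiratory PRM cut, HU.
#' @param exp_cut_init initial value of the learnable expiratory cut, HU.
#' @param input_mode expiratory channel fed to the PRM generator:
#'   `"generated_exp"` (default), `"real_exp"` (registration bypass
#'   ablation), or `"insp_only"` (no expiratory information).
#' @param residual_before_threshold apply the residual correction to the
#'   generated expiratory patch before soft thresholding.
#' @param lr Adam learning rate.
#' @param lr_threshold_factor learning-rate multiplier for the threshold
#'   MLP parameters; the scalar threshold head is sensitive to
#'   co-adaptation with the segmenter, so it trains more slowly.
#' @param class_weights cross-entropy weights for (normal, fSAD,
#'   emphysema).  Emphysema occupies a few percent of the lung at most,
#'   so its term is up-weighted; fSAD is left unweighted because
#'   up-weighting an ambiguous class shifts the decision boundary rather
#'   than accelerating learning.
#' @param mlp_hidden hidden width of the threshold MLP.
#' @return Object of class `net_config`.
#' @export
net_config <- function(unet_depth = 3, base_channels = 16, patch_size = 48,
                       use_refiner = TRUE, use_threshold_head = TRUE,
                       use_fusion = TRUE,
                       adv_type = c("least-squares", "cross-entropy"),
                       lambda_l1 = 100, lambda_consistency = 1,
                       lambda_residual = 1, soft_tau = 20,
                       insp_cut = -950, exp_cut_init = -856,
                       input_mode = c("generated_exp", "real_exp",
                                      "insp_only"),
                       residual_before_threshold = TRUE,
                       lr = 2e-4, lr_threshold_factor = 0.1,
                       class_weights = c(1, 1, 8), mlp_hidden = 16) {
  adv_type <- match.arg(adv_type)
  input_mode <- match.arg(input_mode)
  if (unet_depth < 2) stop("unet_depth must be at least 2")
  if (lambda_l1 < 0 || lambda_consistency < 0 || lambda_residual < 0)
    stop("loss weights must be >= 0")
  if (patch_size %% 2^(unet_depth - 1) != 0)
    stop("incompatible patch size and network stride")
  structure(list(unet_depth = unet_depth, base_channels = base_channels,
                 patch_size = patch_size, use_refiner = use_refiner,
                 use_threshold_head = use_threshold_head,
                 use_fusion = use_fusion, adv_type = adv_type,
                 lambda_l1 = lambda_l1,
                 lambda_consistency = lambda_consistency,
                 lambda_residual = lambda_residual, soft_tau = soft_tau,
                 insp_cut = insp_cut, exp_cut_init = exp_cut_init,
                 input_mode = input_mode,
                 residual_before_threshold = residual_before_threshold,
                 lr = lr, lr_threshold_factor = lr_threshold_factor,
                 class_weights = class_weights, mlp_hidden = mlp_hidden),
            class = "net_config")
}

#' Build the network bundle
#'
#' Instantiates the coarse expiratory generator G1 (inspiratory patch to
#' expiratory patch, residual-style: output = input + learned delta), the
#' conditional refiner G2 ((inspiratory, coarse expiratory) to refined
#' expiratory, identity at initialization), the shared conditional patch
#' discriminator, and the PRM generator ((inspiratory, expiratory) to
#' class logits + HU residual + threshold offset).  Uses the current RNG
#' state; seed it for reproducible builds.
#'
#' @param cfg a [net_config].
#' @return Object of class `prm_networks`: parameter lists `g1`, `g2`,
#'   `d`, `prm` plus the config.
#' @export
build_networks <- function(cfg = net_config()) {
  stopifnot(inherits(cfg, "net_config"))
  g1 <- unet_init(1, 1, cfg$unet_depth, cfg$base_channels,
                  zero_main_head = TRUE)
  g2 <- unet_init(2, 1, cfg$unet_depth, cfg$base_channels,
                  zero_main_head = TRUE)
  d <- disc_init(2, cfg$base_channels)
  prm <- unet_init(2, 3, cfg$unet_depth, cfg$base_channels,
                   residual_head = TRUE,
                   threshold_head = cfg$use_threshold_head,
                   mlp_hidden = cfg$mlp_hidden)
  structure(list(g1 = g1, g2 = g2, d = d, prm = prm, cfg = cfg),
            class = "prm_networks")
}

#' Adversarial and reconstruction losses of the expiratory generator
#'
#' For `"least-squares"` the discriminator outputs are raw scores with
#' real label 1 and fake label 0; for `"cross-entropy"` they are
#' probabilities.  `adv_D` averages the real and fake discriminator
#' terms; the total generator objective is `adv_G + lambda_l1 * l1`.
#'
#' @param real_exp,fake_exp real and generated expiratory patches (HU).
#' @param d_real,d_fake discriminator outputs on the real and fake pair.
#' @param adv_type adversarial loss family.
#' @param lambda_l1 L1 weight used for `total_G`.
#' @return List `adv_G`, `adv_D`, `l1` (mean absolute HU error),
#'   `total_G`.
#' @export
gan_losses <- function(real_exp, fake_exp, d_real, d_fake,
                       adv_type = c("least-squares", "cross-entropy"),
                       lambda_l1 = 100) {
  adv_type <- match.arg(adv_type)
  r <- as.numeric(.as_vox(real_exp)); f <- as.numeric(.as_vox(fake_exp))
  if (length(r) != length(f)) stop("patch shapes differ")
  l1 <- mean(abs(r - f))
  dr <- as.numeric(d_real); df <- as.numeric(d_fake)
  if (adv_type == "least-squares") {
    adv_D <- 0.5 * (mean((dr - 1)^2) + mean(df^2))
    adv_G <- mean((df - 1)^2)
  } else {
    p_r <- pmin(pmax(dr, 1e-7), 1 - 1e-7)
    p_f <- pmin(pmax(df, 1e-7), 1 - 1e-7)
    adv_D <- 0.5 * (mean(-log(p_r)) + mean(-log(1 - p_f)))
    adv_G <- mean(-log(p_f))
  }
  list(adv_G = adv_G, adv_D = adv_D, l1 = l1,
       total_G = adv_G + lambda_l1 * l1 / .HU_SCALE)
}

#' Differentiable (soft) PRM thresholding
#'
#' Smooth relaxation of the PRM rule: with
#' `s_exp = sigmoid((t - HU_exp)/tau)` and
#' `s_insp = sigmoid((HU_insp - insp_cut)/tau)`,
#' `P(fSAD) = s_insp * s_exp`, `P(emphysema) = (1 - s_insp) * s_exp`,
#' `P(normal) = 1 - s_exp`.  As `tau -> 0` the per-voxel argmax equals the
#' hard PRM rule with expiratory cut `t`.
#'
#' @param insp,exp inspiratory and expiratory values, HU (arrays, vectors
#'   or [ct_volume]s of matching size).
#' @param t expiratory threshold, HU.
#' @param tau temperature, HU (> 0).
#' @param insp_cut inspiratory cut, HU.
#' @return Matrix with columns `normal`, `fsad`, `emph`; rows sum to 1.
#' @export
soft_threshold_prm <- function(insp, exp, t, tau = 20, insp_cut = -950) {
  if (tau <= 0) stop("tau must be > 0")
  iv <- as.numeric(.as_vox(insp)); ev <- as.numeric(.as_vox(exp))
  if (length(iv) != length(ev)) stop("patch shapes differ")
  s_exp <- stats::plogis((t - ev) / tau)
  s_insp <- stats::plogis((iv - insp_cut) / tau)
  cbind(normal = 1 - s_exp, fsad = s_insp * s_exp,
        emph = (1 - s_insp) * s_exp)
}

#' Consistency loss between segmentation and threshold PRMs
#'
#' Mean cross-entropy of the segmentation class probabilities against the
#' threshold-derived class probabilities,
#' `-mean_v sum_c q_c(v) log p_c(v)` with `p` the segmentation and `q`
#' the threshold distribution.  Both heads co-train through this term.
#'
#' @param seg_probs,threshold_probs matrices of per-voxel class
#'   probabilities (rows sum to 1).
#' @return Scalar >= 0.
#' @export
consistency_loss <- function(seg_probs, threshold_probs) {
  if (!identical(dim(seg_probs), dim(threshold_probs)))
    stop("probability shapes differ")
  if (max(abs(rowSums(seg_probs) - 1)) > 1e-5 ||
      max(abs(rowSums(threshold_probs) - 1)) > 1e-5)
    stop("probabilities must sum to 1 per voxel")
  p <- pmin(pmax(seg_probs, 1e-7), 1 - 1e-7)
  mean(-rowSums(threshold_probs * log(p)))
}

#' Apply an HU residual correction
#'
#' @param gen_exp generated expiratory patch ([ct_volume] or array, HU).
#' @param residual residual map of the same shape, HU.
#' @return Corrected patch, clamped to the HU range, same type as
#'   `gen_exp`.
#' @export
apply_residual <- function(gen_exp, residual) {
  g <- .as_vox(gen_exp); r <- .as_vox(residual)
  if (!identical(dim(g), dim(r)) && length(g) != length(r))
    stop("shapes differ")
  out <- g + r
  out[out < HU_MIN] <- HU_MIN
  out[out > HU_MAX] <- HU_MAX
  if (inherits(gen_exp, "ct_volume"))
    ct_volume(out, spacing = gen_exp$spacing, origin = gen_exp$origin,
              phase = gen_exp$phase)
  else out
}

#' Fuse segmentation and threshold PRMs
#'
#' Averages the segmentation class probabilities with the one-hot
#' encoding of the threshold-derived PRM and takes the per-voxel argmax;
#' ties break by class priority normal > fSAD > emphysema.  Voxels that
#' are background in the threshold map stay background.
#'
#' @param seg_probs per-voxel probability matrix (columns normal, fSAD,
#'   emphysema) over the full grid, or a 4D array `dim x 3`.
#' @param thr_map threshold-derived [prm_map].
#' @return A fused [prm_map].
#' @export
fuse_prm <- function(seg_probs, thr_map) {
  stopifnot(inherits(thr_map, "prm_map"))
  d <- dim(thr_map$labels)
  if (length(dim(seg_probs)) == 4L) seg_probs <- matrix(seg_probs, prod(d), 3)
  if (nrow(seg_probs) != prod(d)) stop("grid mismatch")
  lab <- as.integer(thr_map$labels)
  onehot <- matrix(0, length(lab), 3)
  inl <- lab > 0L
  onehot[cbind(which(inl), lab[inl])] <- 1
  avg <- (seg_probs + onehot) / 2
  fused <- integer(length(lab))
  fused[inl] <- max.col(avg[inl, , drop = FALSE], ties.method = "first")
  prm_map(array(fused, d), source = "fused", spacing = thr_map$spacing)
}

## ---- internal training machinery ----------------------------------------

.softmax3 <- function(logits) {
  m <- pmax(logits[, 1], pmax(logits[, 2], logits[, 3]))
  e <- exp(logits - m)
  e / rowSums(e)
}

.crop_corner <- function(shape, psize) {
  vapply(1:3, function(a) {
    if (shape[a] <= psize) 1L
    else sample.int(shape[a] - psize + 1L, 1L)
  }, integer(1))
}

.extract_patch <- function(arr, corner, psize) {
  arr[corner[1]:(corner[1] + psize - 1),
      corner[2]:(corner[2] + psize - 1),
      corner[3]:(corner[3] + psize - 1)]
}

## Registered expiratory volume of a phantom sample (exact under the
## phantom's whole-voxel field).
.exp_reg <- function(sample) {
  warp_volume(sample$exp, sample$field)$voxels
}

.disc_grad_out <- function(dout, target, adv_type) {
  n <- length(dout)
  if (adv_type == "least-squares") (dout - target) / n
  else (stats::plogis(dout) - target) / n  # BCE-with-logits
}

.disc_loss <- function(dout, target, adv_type) {
  if (adv_type == "least-squares") 0.5 * mean((dout - target)^2)
  else {
    p <- stats::plogis(dout)
    mean(-(target * log(pmax(p, 1e-12)) +
             (1 - target) * log(pmax(1 - p, 1e-12))))
  }
}

#' Train the cascaded expiratory generator
#'
#' Alternating discriminator/generator updates on random patches from
#' paired inspiratory and registered expiratory volumes: the coarse
#' generator and the refiner are each supervised by an L1 term weighted
#' `lambda_l1` plus the adversarial term from the shared conditional
#' discriminator.  Training is deterministic under a fixed seed.
#'
#' @param samples list of [generate_phantom()] samples (or lists with
#'   elements `insp`, `exp`, `field`).
#' @param cfg a [net_config].
#' @param seed integer seed.
#' @param epochs training epochs (one patch per sample per epoch).
#' @param lr Adam learning rate (default from `cfg`).
#' @return Object of class `expgen_checkpoint`: parameter lists `g1`,
#'   `g2`, `d`, the config, seed, and a per-epoch `history` data frame
#'   (adversarial and L1 losses, HU).
#' @export
train_expiratory_generator <- function(samples, cfg = net_config(),
                                       seed = 1L, epochs = 20,
                                       lr = cfg$lr) {
  set.seed(seed)
  nets <- build_networks(cfg)
  g1 <- nets$g1; g2 <- nets$g2; d <- nets$d
  st_g1 <- adam_state(g1); st_g2 <- adam_state(g2); st_d <- adam_state(d)
  P <- cfg$patch_size
  shape3 <- rep(P, 3L)
  dat <- lapply(samples, function(s)
    list(insp = s$insp$voxels, expr = .exp_reg(s)))
  hist <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(length(dat))
    acc <- c(adv_D = 0, adv_G1 = 0, adv_G2 = 0, l1_g1 = 0, l1_g2 = 0)
    for (si in ord) {
      s <- dat[[si]]
      corner <- .crop_corner(dim(s$insp), P)
      X <- matrix(.to_net(.extract_patch(s$insp, corner, P)), ncol = 1)
      R <- matrix(.to_net(.extract_patch(s$expr, corner, P)), ncol = 1)
      f1 <- unet_fwd(g1, X, shape3)
      fake1 <- X + f1$out
      use2 <- isTRUE(cfg$use_refiner)
      if (use2) {
        f2 <- unet_fwd(g2, cbind(X, fake1), shape3)
        fake2 <- fake1 + f2$out
      }
      ## --- discriminator update
      dr <- disc_fwd(d, cbind(X, R), shape3)
      dfk1 <- disc_fwd(d, cbind(X, fake1), shape3)
      nfake <- if (use2) 2 else 1
      gd <- disc_bwd(d, dr, .disc_grad_out(dr$out, 1, cfg$adv_type) / 2)$grads
      gf1 <- disc_bwd(d, dfk1,
                      .disc_grad_out(dfk1$out, 0, cfg$adv_type) / (2 * nfake))$grads
      gsum <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                     gd, gf1, SIMPLIFY = FALSE)
      ld <- 0.5 * .disc_loss(dr$out, 1, cfg$adv_type) +
        0.5 * .disc_loss(dfk1$out, 0, cfg$adv_type) / nfake
      if (use2) {
        dfk2 <- disc_fwd(d, cbind(X, fake2), shape3)
        gf2 <- disc_bwd(d, dfk2,
                        .disc_grad_out(dfk2$out, 0, cfg$adv_type) / (2 * nfake))$grads
        gsum <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                       gsum, gf2, SIMPLIFY = FALSE)
        ld <- ld + 0.5 * .disc_loss(dfk2$out, 0, cfg$adv_type) / nfake
      }
      up <- adam_step(d, gsum, st_d, lr)
      d <- up$par; st_d <- up$state
      ## --- G1 update (adversarial through the refreshed D + L1)
      da <- disc_fwd(d, cbind(X, fake1), shape3)
      gadv <- if (cfg$adv_type == "least-squares")
        2 * (da$out - 1) / length(da$out)
      else (stats::plogis(da$out) - 1) / length(da$out)
      dXd <- disc_bwd(d, da, gadv, want_dx = TRUE)$dX
      l1_1 <- mean(abs(fake1 - R))
      dfake1 <- dXd[, 2, drop = FALSE] +
        cfg$lambda_l1 * sign(fake1 - R) / length(fake1)
      gg1 <- unet_bwd(g1, f1, dfake1)$grads
      up <- adam_step(g1, gg1, st_g1, lr)
      g1 <- up$par; st_g1 <- up$state
      adv_g1 <- if (cfg$adv_type == "least-squares") mean((da$out - 1)^2)
      else mean(-log(pmax(stats::plogis(da$out), 1e-12)))
      ## --- G2 update
      l1_2 <- NA_real_; adv_g2 <- NA_real_
      if (use2) {
        da2 <- disc_fwd(d, cbind(X, fake2), shape3)
        gadv2 <- if (cfg$adv_type == "least-squares")
          2 * (da2$out - 1) / length(da2$out)
        else (stats::plogis(da2$out) - 1) / length(da2$out)
        dXd2 <- disc_bwd(d, da2, gadv2, want_dx = TRUE)$dX
        l1_2 <- mean(abs(fake2 - R))
        dfake2 <- dXd2[, 2, drop = FALSE] +
          cfg$lambda_l1 * sign(fake2 - R) / length(fake2)
        gg2 <- unet_bwd(g2, f2, dfake2)$grads
        up <- adam_step(g2, gg2, st_g2, lr)
        g2 <- up$par; st_g2 <- up$state
        adv_g2 <- if (cfg$adv_type == "least-squares") mean((da2$out - 1)^2)
        else mean(-log(pmax(stats::plogis(da2$out), 1e-12)))
      }
      if (!all(is.finite(c(ld, l1_1, adv_g1))))
        stop("training diverged: non-finite loss")
      acc <- acc + c(ld, adv_g1, ifelse(is.na(adv_g2), 0, adv_g2),
                     l1_1, ifelse(is.na(l1_2), 0, l1_2))
    }
    acc <- acc / length(dat)
    hist <- rbind(hist, data.frame(
      epoch = ep, adv_D = acc[1], adv_G1 = acc[2], adv_G2 = acc[3],
      l1_g1_hu = acc[4] * .HU_SCALE, l1_g2_hu = acc[5] * .HU_SCALE))
  }
  rownames(hist) <- NULL
  structure(list(g1 = g1, g2 = g2, d = d, cfg = cfg, seed = seed,
                 epochs = epochs, history = hist),
            class = "expgen_checkpoint")
}

## Generated expiratory patch (normalized units) from an expgen
## checkpoint; no gradients.
.gen_exp_patch <- function(ck, X, shape3) {
  f1 <- unet_fwd(ck$g1, X, shape3)
  fake <- X + f1$out
  if (isTRUE(ck$cfg$use_refiner)) {
    f2 <- unet_fwd(ck$g2, cbind(X, fake), shape3)
    fake <- fake + f2$out
  }
  fake
}

## Whole-volume generated expiratory image (normalized units): the
## generators are fully convolutional, so volumes whose sides are
## divisible by the network stride run in a single forward pass.
.gen_exp_volume <- function(ck, vox_hu) {
  d <- dim(vox_hu)
  stride <- 2^(ck$cfg$unet_depth - 1)
  if (any(d %% stride != 0))
    stop("volume sides must be divisible by the network stride")
  X <- matrix(.to_net(vox_hu), ncol = 1)
  array(.gen_exp_patch(ck, X, d), d)
}

#' Train the PRM generator
#'
#' Minimizes the lung-masked segmentation cross-entropy against the
#' ground-truth PRM, plus `lambda_consistency` times the consistency loss
#' between the segmentation probabilities and the PRM derived from the
#' learnable expiratory threshold, plus `lambda_residual` times an L1
#' supervision of the HU residual head.  The expiratory input channel is
#' taken from a frozen expiratory generator (`input_mode = "generated_exp"`),
#' the real registered expiratory volume (`"real_exp"`), or omitted
#' (`"insp_only"`).
#'
#' @param samples list of phantom samples with ground-truth PRM.
#' @param expgen an `expgen_checkpoint` (required for
#'   `input_mode = "generated_exp"`).
#' @param cfg a [net_config].
#' @param seed integer seed.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @return Object of class `prmgen_checkpoint` with the parameter list,
#'   config, per-epoch `history` (cross-entropy, consistency, residual
#'   losses and the learned threshold, HU) and `threshold`, the final
#'   learned expiratory threshold in HU.
#' @export
train_prm_generator <- function(samples, expgen = NULL, cfg = net_config(),
                                seed = 1L, epochs = 30, lr = cfg$lr) {
  if (cfg$input_mode == "generated_exp" && is.null(expgen))
    stop("input_mode 'generated_exp' requires an expiratory generator")
  set.seed(seed)
  prm <- unet_init(2, 3, cfg$unet_depth, cfg$base_channels,
                   residual_head = TRUE,
                   threshold_head = cfg$use_threshold_head,
                   mlp_hidden = cfg$mlp_hidden)
  st <- adam_state(prm)
  st_thr <- adam_state(prm[names(prm) %in% c("thr1", "thr2")])
  P <- cfg$patch_size
  shape3 <- rep(P, 3L)
  dat <- lapply(samples, function(s) {
    out <- list(insp = s$insp$voxels, expr = .exp_reg(s),
                truth = s$truth$labels, lung = s$mask$voxels)
    if (cfg$input_mode == "generated_exp")
      out$gen <- .gen_exp_volume(expgen, out$insp)
    out
  })
  hist <- NULL
  t_cur <- cfg$exp_cut_init
  for (ep in seq_len(epochs)) {
    ord <- sample(length(dat))
    acc <- c(ce = 0, cons = 0, res = 0)
    for (si in ord) {
      s <- dat[[si]]
      corner <- .crop_corner(dim(s$insp), P)
      insp_hu <- .extract_patch(s$insp, corner, P)
      X <- matrix(.to_net(insp_hu), ncol = 1)
      Rhu <- .extract_patch(s$expr, corner, P)
      Rn <- matrix(.to_net(Rhu), ncol = 1)
      E <- switch(cfg$input_mode,
                  generated_exp = matrix(.extract_patch(s$gen, corner, P),
                                         ncol = 1),
                  real_exp = Rn,
                  insp_only = matrix(0, length(X), 1))
      lung <- as.numeric(.extract_patch(s$lung, corner, P))
      truth <- as.integer(.extract_patch(s$truth, corner, P))
      nl <- sum(lung)
      if (nl < 10) next
      fw <- unet_fwd(prm, cbind(X, E), shape3)
      probs <- .softmax3(fw$out)
      onehot <- matrix(0, length(truth), 3)
      inl <- truth > 0L
      onehot[cbind(which(inl), truth[inl])] <- 1
      wl <- lung / nl
      ## class-weighted cross-entropy over lung voxels
      cw <- cfg$class_weights
      wv <- wl * ifelse(inl, cw[pmax(truth, 1L)], 0)
      wv <- wv / sum(wv) * 1  # renormalize to a mean-CE scale
      ce <- -sum(wv * ifelse(inl, log(pmax(probs[cbind(seq_along(truth),
        pmax(truth, 1L))], 1e-12)), 0))
      dlogits <- (probs - onehot) * wv
      ## residual head supervision (normalized units, lung voxels only:
      ## outside the lung the expiratory channel needs no correction and
      ## unmasked noise gradients drown the segmentation signal)
      resn <- fw$res
      l_res <- sum(wl * abs(E + resn - Rn))
      dres <- cfg$lambda_residual * sign(E + resn - Rn) * wl
      ## consistency with the threshold-derived PRM
      l_cons <- 0; dt <- 0
      if (cfg$use_threshold_head) {
        t_cur <- cfg$exp_cut_init + fw$thr$toff
        exp_thr_hu <- .from_net(
          E + if (cfg$residual_before_threshold) resn else 0)
        s_e <- stats::plogis((t_cur - exp_thr_hu) / cfg$soft_tau)
        s_i <- stats::plogis((insp_hu - cfg$insp_cut) / cfg$soft_tau)
        thr_probs <- cbind(1 - s_e, as.numeric(s_i) * as.numeric(s_e),
                           (1 - as.numeric(s_i)) * as.numeric(s_e))
        pc <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
        l_cons <- sum(wl * -rowSums(thr_probs * log(pc)))
        ## gradient into the segmentation logits
        dlogits <- dlogits + cfg$lambda_consistency *
          (probs - thr_probs) * wl
        ## gradient into t (and optionally the residual) through s_e
        dthr <- -log(pc) * wl  # d l_cons / d thr_probs
        bracket <- dthr[, 2] * as.numeric(s_i) +
          dthr[, 3] * (1 - as.numeric(s_i)) - dthr[, 1]
        sprime <- as.numeric(s_e) * (1 - as.numeric(s_e)) / cfg$soft_tau
        dt <- cfg$lambda_consistency * sum(bracket * sprime)
        if (cfg$residual_before_threshold) {
          dexp_hu <- -cfg$lambda_consistency * bracket * sprime
          dres <- dres + matrix(dexp_hu, ncol = 1) * .HU_SCALE
        }
      }
      bw <- unet_bwd(prm, fw, dlogits, dRes = dres, dT = dt)
      g_thr <- bw$grads[names(bw$grads) %in% c("thr1", "thr2")]
      g_main <- bw$grads[!names(bw$grads) %in% c("thr1", "thr2")]
      up <- adam_step(prm, g_main, st, lr)
      prm <- up$par; st <- up$state
      if (length(g_thr)) {
        fac <- if (is.null(cfg$lr_threshold_factor)) 0.1
        else cfg$lr_threshold_factor
        up <- adam_step(prm, g_thr, st_thr, lr * fac)
        prm[names(up$par)] <- up$par[names(up$par)]
        st_thr <- up$state
      }
      if (!all(is.finite(c(ce, l_cons, l_res))))
        stop("training diverged: non-finite loss")
      acc <- acc + c(ce, l_cons, l_res)
    }
    acc <- acc / length(dat)
    hist <- rbind(hist, data.frame(epoch = ep, ce = acc[1], cons = acc[2],
                                   res = acc[3],
                                   threshold_hu = as.numeric(t_cur)))
  }
  rownames(hist) <- NULL
  structure(list(par = prm, cfg = cfg, seed = seed, epochs = epochs,
                 history = hist, threshold = as.numeric(t_cur)),
            class = "prmgen_checkpoint")
}

## Cosine (Hann) blending window for one axis with a small floor so that
## normalization is exact for single-tile coverage.
.hann1 <- function(n) 0.01 + 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)

#' Predict PRM from a single inspiratory volume
#'
#' Sliding-window inference: the cascaded generator synthesizes the
#' expiratory volume tile by tile, the PRM generator produces class
#' logits, an HU residual and a per-volume expiratory threshold, tiles
#' are blended with a cosine window, and the final map fuses the
#' segmentation argmax probabilities with the PRM obtained by hard
#' thresholding the (residual-corrected) generated expiratory volume at
#' the learned threshold.  Labels are zeroed outside the lung mask.
#'
#' @param insp inspiratory [ct_volume].
#' @param mask [lung_mask].
#' @param expgen trained `expgen_checkpoint`.
#' @param prmgen trained `prmgen_checkpoint`.
#' @param overlap tile overlap in voxels (>= 8).
#' @param gen_exp optional precomputed generated expiratory [ct_volume]
#'   (skips the generator tiles; useful for ablations sharing one
#'   generator).
#' @return List: `gen_exp` (generated expiratory [ct_volume]), `pred`
#'   (predicted [prm_map]), `seg_probs` (N x 3 matrix), `threshold`
#'   (learned expiratory cut, HU), `thr_map` (threshold-derived
#'   [prm_map]).
#' @export
predict_prm <- function(insp, mask, expgen, prmgen, overlap = 8,
                        gen_exp = NULL) {
  stopifnot(inherits(insp, "ct_volume"), inherits(mask, "lung_mask"))
  cfg <- prmgen$cfg
  P <- cfg$patch_size
  d0 <- dim(insp$voxels)
  pad <- pmax(P - d0, 0L)
  vox <- insp$voxels
  genv <- if (!is.null(gen_exp)) .to_net(.as_vox(gen_exp)) else NULL
  if (any(pad > 0L)) {
    padded <- array(-1000, d0 + pad)
    padded[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- vox
    vox <- padded
    if (!is.null(genv)) {
      pg <- array(.to_net(-1000), d0 + pad)
      pg[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- genv
      genv <- pg
    }
  }
  d <- dim(vox)
  starts <- lapply(1:3, function(a) {
    if (d[a] == P) 1L
    else unique(c(seq(1L, d[a] - P + 1L, by = P - overlap), d[a] - P + 1L))
  })
  n <- prod(d)
  shape3 <- rep(P, 3L)
  w1 <- .hann1(P)
  w3 <- as.numeric(outer(outer(w1, w1), w1))
  acc_w <- numeric(n)
  acc_exp <- numeric(n)
  acc_res <- numeric(n)
  acc_log <- matrix(0, n, 3)
  ts <- numeric(0)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    corner <- c(sx, sy, sz)
    insp_hu <- .extract_patch(vox, corner, P)
    X <- matrix(.to_net(insp_hu), ncol = 1)
    E <- if (!is.null(genv)) matrix(.extract_patch(genv, corner, P), ncol = 1)
    else switch(cfg$input_mode,
                generated_exp = .gen_exp_patch(expgen, X, shape3),
                real_exp = stop("real_exp mode needs the expiratory scan; use classify_prm"),
                insp_only = matrix(0, length(X), 1))
    fw <- unet_fwd(prmgen$par, cbind(X, E), shape3)
    ## linear indices of the patch voxels in the padded volume
    ix <- corner[1]:(corner[1] + P - 1)
    iy <- corner[2]:(corner[2] + P - 1)
    iz <- corner[3]:(corner[3] + P - 1)
    lin <- as.vector(outer(outer(ix, (iy - 1) * d[1], `+`),
                           (iz - 1) * d[1] * d[2], `+`))
    acc_w[lin] <- acc_w[lin] + w3
    acc_exp[lin] <- acc_exp[lin] + w3 * as.numeric(E)
    acc_res[lin] <- acc_res[lin] + w3 * as.numeric(fw$res)
    acc_log[lin, ] <- acc_log[lin, ] + w3 * fw$out
    if (cfg$use_threshold_head)
      ts <- c(ts, cfg$exp_cut_init + fw$thr$toff)
  }
  gen_exp <- .from_net(acc_exp / acc_w)
  res_hu <- acc_res / acc_w * .HU_SCALE  # residual is a difference: scale only
  logits <- acc_log / acc_w
  ## crop padding away
  keep <- as.vector(outer(outer(seq_len(d0[1]), (seq_len(d0[2]) - 1) * d[1],
                                `+`), (seq_len(d0[3]) - 1) * d[1] * d[2], `+`))
  gen_exp <- array(gen_exp[keep], d0)
  res_hu <- array(res_hu[keep], d0)
  logits <- logits[keep, , drop = FALSE]
  probs <- .softmax3(logits)
  t_hat <- if (cfg$use_threshold_head) mean(ts) else -856
  gen_vol <- ct_volume(gen_exp, spacing = insp$spacing,
                       origin = insp$origin, phase = "generated-expiratory")
  exp_ref <- if (cfg$residual_before_threshold)
    apply_residual(gen_vol, res_hu) else gen_vol
  thr_map <- classify_prm(insp, exp_ref, mask,
                          prm_thresholds(cfg$insp_cut, t_hat),
                          source = "threshold-derived")$map
  m <- as.numeric(mask$voxels)
  if (isTRUE(cfg$use_fusion) && cfg$use_threshold_head) {
    pred <- fuse_prm(probs, thr_map)
  } else {
    lab <- max.col(probs, ties.method = "first") * (m > 0)
    pred <- prm_map(array(as.integer(lab), d0), source = "predicted",
                    spacing = insp$spacing)
  }
  pred$labels[!mask$voxels] <- 0L
  list(gen_exp = gen_vol, pred = pred, seg_probs = probs,
       threshold = t_hat, thr_map = thr_map, residual = res_hu)
}
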