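#' Synthetic paired-CT phantom specification
#'
#' Parameters of the synthetic inspiratory/expiratory lung phantom.  The
#' phantom emulates the attenuation logic PRM assumes: emphysema is low
#' attenuation in both phases, fSAD has normal inspiratory attenuation but
#' trapped (low) expiratory attenuation, and normal parenchyma regains
#' density at expiration.
#'
#' Default noiseless class means (HU), inspiratory / expiratory:
#' normal -880 / -700, fSAD -880 / -900, emphysema -975 / -965;
#' body +40, background -1000.
#'
#' @param shape grid size, length-3 (default 64^3).
#' @param spacing voxel size in mm (default 2 mm isotropic).
#' @param target_fsad_fraction target fSAD percentage of lung volume.
#' @param target_emph_fraction target emphysema percentage of lung volume.
#' @param blob_radius range of lesion ellipsoid semi-axes, voxels.
#' @param fraction_tol tolerance on realized class fractions, percentage
#'   points.
#' @param hu_model named list of per-class HU means (see Details).
#' @param compression axial compression factor of the expiration model
#'   (default 0.90; 1 = no compression).
#' @param perturb_amp amplitude bound of the smooth random deformation
#'   perturbation, voxels (default 2).
#' @param perturb_spacing control-grid spacing of the perturbation, voxels.
#' @param noise_sd additive Gaussian noise per phase, HU (default 10).
#' @param seed integer seed fixing all randomness.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                         target_fsad_fraction = 20, target_emph_fraction = 5,
                         blob_radius = c(4, 9), fraction_tol = 3,
                         hu_model = NULL, compression = 0.90,
                         perturb_amp = 2, perturb_spacing = 16,
                         noise_sd = 10, seed = 1L) {
  if (target_fsad_fraction < 0 || target_emph_fraction < 0 ||
      target_fsad_fraction + target_emph_fraction >= 100)
    stop("class fraction targets must be >= 0 and sum below 100")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  default_hu <- list(
    normal = c(insp = -880, exp = -700),
    fsad = c(insp = -880, exp = -900),
    emph = c(insp = -975, exp = -965),
    body = c(insp = 40, exp = 40),
    background = c(insp = -1000, exp = -1000))
  if (is.null(hu_model)) hu_model <- default_hu
  else hu_model <- utils::modifyList(default_hu, hu_model)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 target_fsad_fraction = target_fsad_fraction,
                 target_emph_fraction = target_emph_fraction,
                 blob_radius = blob_radius, fraction_tol = fraction_tol,
                 hu_model = hu_model, compression = compression,
                 perturb_amp = perturb_amp,
                 perturb_spacing = perturb_spacing,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Logical ellipsoid on the grid.
.ellipsoid <- function(shape, center, semi) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

## Body + two-lung geometry; returns list(body, lung) logical arrays.
.phantom_geometry <- function(shape) {
  body <- .ellipsoid(shape, shape * c(0.50, 0.50, 0.50),
                     shape * c(0.42, 0.36, 0.46))
  lungL <- .ellipsoid(shape, shape * c(0.30, 0.50, 0.52),
                      shape * c(0.17, 0.23, 0.30))
  lungR <- .ellipsoid(shape, shape * c(0.70, 0.50, 0.52),
                      shape * c(0.17, 0.23, 0.30))
  lung <- (lungL | lungR) & body
  list(body = body, lung = lung)
}

## Greedy ellipsoidal blob placement for one lesion class.  Converts
## normal-lung voxels to `class_id` until the realized percentage is within
## `tol` points of `target`.
.add_blobs <- function(tissue, lung, target, tol, rr, class_id,
                       max_tries = 400L) {
  n_lung <- sum(lung)
  frac <- function() 100 * sum(tissue == class_id) / n_lung
  if (target <= 0) return(tissue)
  shape <- dim(tissue)
  centers <- which(lung)
  tries <- 0L
  while (frac() < target - tol / 2 && tries < max_tries) {
    tries <- tries + 1L
    ctr <- arrayInd(sample(centers, 1L), shape)
    semi <- stats::runif(3, rr[1], rr[2])
    blob <- .ellipsoid(shape, as.numeric(ctr), semi)
    sel <- blob & lung & tissue == 1L
    if (!any(sel)) next
    gain <- 100 * sum(sel) / n_lung
    if (frac() + gain > target + tol) {
      ## shrink towards the remaining deficit
      scale <- sqrt((target - frac()) / gain)
      semi <- pmax(semi * max(scale, 0.3), 1.5)
      blob <- .ellipsoid(shape, as.numeric(ctr), semi)
      sel <- blob & lung & tissue == 1L
      if (!any(sel) || frac() + 100 * sum(sel) / n_lung > target + tol) next
    }
    tissue[sel] <- class_id
  }
  if (abs(frac() - target) > tol)
    stop("lesion fraction target unreachable with configured blob sizes")
  tissue
}

#' Sample a per-voxel tissue-class grid
#'
#' Partitions the lung interior into normal parenchyma, fSAD, and emphysema
#' by unions of random ellipsoidal blobs, placed greedily until the realized
#' class fractions are within `fraction_tol` percentage points of the spec
#' targets.  Uses the current RNG state.
#'
#' @param spec a [phantom_spec].
#' @param lung optional logical lung array; generated from the spec
#'   geometry when missing.
#' @return Integer array: 0 outside lung, 1 normal, 2 fSAD, 3 emphysema.
#' @export
sample_lesion_field <- function(spec, lung = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(lung)) lung <- .phantom_geometry(spec$shape)$lung
  tissue <- array(0L, spec$shape)
  tissue[lung] <- 1L
  tissue <- .add_blobs(tissue, lung, spec$target_emph_fraction,
                       spec$fraction_tol, spec$blob_radius, 3L)
  tissue <- .add_blobs(tissue, lung, spec$target_fsad_fraction,
                       spec$fraction_tol, spec$blob_radius, 2L)
  tissue
}

## Noiseless HU volume for one phase from the tissue grid + geometry.
.hu_volume <- function(tissue, body, hu, phase) {
  vol <- array(hu$background[[phase]], dim(tissue))
  vol[body] <- hu$body[[phase]]
  vol[tissue == 1L] <- hu$normal[[phase]]
  vol[tissue == 2L] <- hu$fsad[[phase]]
  vol[tissue == 3L] <- hu$emph[[phase]]
  vol
}

## Integer per-column axial shift field of the expiration model:
## compression anchored at the lung base plus a smooth random in-plane
## perturbation, rounded to whole voxels (constant along z), so the pair
## round-trips exactly under trilinear warping.
.expiration_shift <- function(spec, lung) {
  shape <- spec$shape
  zs <- apply(lung, c(1, 2), function(col) {
    w <- which(col)
    if (length(w) == 0) NA_real_ else max(w)
  })
  ## compression anchored at the inferior volume face: a column whose
  ## apical lung voxel sits at height z moves by (k - 1) * (z - 1)
  s_cont <- (spec$compression - 1) * pmax(zs - 1, 0)
  s_cont[is.na(s_cont)] <- mean(s_cont, na.rm = TRUE)
  if (all(is.na(s_cont))) s_cont[] <- 0
  ## smooth perturbation from a coarse control grid, bilinear-upsampled
  if (spec$perturb_amp > 0) {
    nc <- pmax(ceiling(shape[1:2] / spec$perturb_spacing) + 1L, 2L)
    ctrl <- matrix(stats::rnorm(prod(nc), 0, spec$perturb_amp / 2), nc[1], nc[2])
    ctrl <- pmin(pmax(ctrl, -spec$perturb_amp), spec$perturb_amp)
    gx <- seq(1, nc[1], length.out = shape[1])
    gy <- seq(1, nc[2], length.out = shape[2])
    x0 <- pmin(floor(gx), nc[1] - 1L); fx <- gx - x0
    y0 <- pmin(floor(gy), nc[2] - 1L); fy <- gy - y0
    p <- outer(seq_len(shape[1]), seq_len(shape[2]), function(i, j) {
      c00 <- ctrl[cbind(x0[i], y0[j])];     c10 <- ctrl[cbind(x0[i] + 1, y0[j])]
      c01 <- ctrl[cbind(x0[i], y0[j] + 1)]; c11 <- ctrl[cbind(x0[i] + 1, y0[j] + 1)]
      (c00 * (1 - fx[i]) + c10 * fx[i]) * (1 - fy[j]) +
        (c01 * (1 - fx[i]) + c11 * fx[i]) * fy[j]
    })
  } else p <- matrix(0, shape[1], shape[2])
  round(s_cont + p)
}

#' Apply the expiration model to a tissue grid
#'
#' Produces the paired volumes: the inspiratory volume from the per-class
#' inspiratory means, and the expiratory volume as the density-shifted
#' volume displaced toward the inferior face by the axial compression
#' profile composed with a smooth random perturbation.  Independent
#' Gaussian noise is added per phase.  The returned deformation field,
#' defined on the inspiratory grid, carries each inspiratory voxel to its
#' expiratory-space sample position, so
#' `warp_volume(exp, field)` re-aligns the expiratory volume exactly.
#'
#' @param tissue tissue-class grid from [sample_lesion_field()].
#' @param spec a [phantom_spec].
#' @return List with `insp`, `exp` ([ct_volume]s) and `field`
#'   ([deformation_field]).
#' @export
apply_expiration_model <- function(tissue, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  geom <- .phantom_geometry(shape)
  lung <- tissue > 0L
  insp_clean <- .hu_volume(tissue, geom$body, spec$hu_model, "insp")
  exp_insp_clean <- .hu_volume(tissue, geom$body, spec$hu_model, "exp")
  S <- .expiration_shift(spec, lung)
  ## out-of-grid check for lung voxels
  zmin_col <- apply(lung, c(1, 2), function(col)
    if (any(col)) min(which(col)) else NA_integer_)
  bad <- !is.na(zmin_col) & (zmin_col + S < 1 |
    apply(lung, c(1, 2), function(col) if (any(col)) max(which(col)) else NA_integer_) + S > shape[3])
  if (any(bad, na.rm = TRUE)) stop("deformation pushes lung outside the grid")
  ## exp column z' takes the value of exp_insp column at z' - S
  exp_clean <- array(spec$hu_model$background[["exp"]], shape)
  d3 <- shape[3]
  for (s in unique(as.vector(S))) {
    cols <- which(S == s)  # linear indices in the (x, y) plane
    src <- seq_len(d3) - s
    src <- pmin(pmax(src, 1L), d3)  # replicate at the column ends
    ## exp_clean[cols, z'] <- exp_insp_clean[cols, src[z']]
    plane_n <- prod(shape[1:2])
    for (zp in seq_len(d3)) {
      exp_clean[cols + (zp - 1L) * plane_n] <-
        exp_insp_clean[cols + (src[zp] - 1L) * plane_n]
    }
  }
  disp <- array(0, c(shape, 3))
  disp[, , , 3] <- array(rep(S, d3), c(shape[1:2], d3))
  field <- deformation_field(disp, spacing = spec$spacing)
  insp <- ct_volume(insp_clean + stats::rnorm(length(insp_clean), 0, spec$noise_sd),
                    spacing = spec$spacing, phase = "inspiratory")
  expv <- ct_volume(exp_clean + stats::rnorm(length(exp_clean), 0, spec$noise_sd),
                    spacing = spec$spacing, phase = "expiratory")
  list(insp = insp, exp = expv, field = field)
}

#' Generate a complete paired-CT phantom
#'
#' Composes the geometry, lesion sampling, and expiration model under the
#' spec's seed.  The ground-truth PRM equals the tissue-class grid inside
#' the lung.
#'
#' @param spec a [phantom_spec].
#' @return Object of class `phantom_sample`: `insp`, `exp` ([ct_volume]s),
#'   `mask` ([lung_mask]), `truth` ([prm_map]), `field`
#'   ([deformation_field]), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32), seed = 1))
#' prm_fractions(ph$truth)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  geom <- .phantom_geometry(spec$shape)
  tissue <- sample_lesion_field(spec, geom$lung)
  pair <- apply_expiration_model(tissue, spec)
  structure(list(insp = pair$insp, exp = pair$exp,
                 mask = lung_mask(tissue > 0L, spacing = spec$spacing),
                 truth = prm_map(tissue, source = "ground-truth",
                                 spacing = spec$spacing),
                 field = pair$field, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  fr <- prm_fractions(x$truth)
  cat(sprintf(paste0("<phantom_sample> %s grid, lung %d voxels ",
                     "(fSAD %.1f%%, emphysema %.1f%%), noise sd %g HU\n"),
              paste(x$spec$shape, collapse = "x"), sum(x$mask$voxels),
              fr$pct_fsad, fr$pct_emph, x$spec$noise_sd))
  invisible(x)
}
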