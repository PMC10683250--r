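#' PRM classification thresholds
#'
#' The canonical PRM decision thresholds: lung voxels are functional small
#' airway disease (fSAD) when inspiratory attenuation is above `insp_cut`
#' and expiratory attenuation below `exp_cut`; emphysema when both are
#' below their cut; all other lung voxels are normal parenchyma.
#'
#' Boundary convention: an inspiratory value exactly equal to `insp_cut`
#' takes the fSAD branch; an expiratory value exactly equal to `exp_cut`
#' is not trapped (normal branch).
#'
#' @param insp_cut inspiratory cut in HU (default -950).
#' @param exp_cut expiratory cut in HU (default -856); must exceed
#'   `insp_cut`.
#' @return Object of class `prm_thresholds`.
#' @export
prm_thresholds <- function(insp_cut = -950, exp_cut = -856) {
  if (!(insp_cut < exp_cut)) stop("insp_cut must be below exp_cut")
  structure(list(insp_cut = insp_cut, exp_cut = exp_cut),
            class = "prm_thresholds")
}

#' Voxel-wise PRM classification
#'
#' Classifies every lung voxel of a registered inspiratory/expiratory pair
#' into normal parenchyma, fSAD, or emphysema by the joint attenuation
#' rule, and reports the volume percentage of each class.
#'
#' @param insp inspiratory [ct_volume].
#' @param exp_reg expiratory [ct_volume], already registered onto the
#'   inspiratory grid.
#' @param mask [lung_mask] on the same grid.
#' @param thr [prm_thresholds].
#' @param source provenance tag recorded in the returned map.
#' @return Object of class `prm_result`: fields `map` ([prm_map]),
#'   `pct_normal`, `pct_fsad`, `pct_emph` (percent of lung volume) and
#'   `n_lung` (lung voxel count).
#' @examples
#' insp <- ct_volume(array(-900, c(2, 2, 2)))
#' expv <- ct_volume(array(-900, c(2, 2, 2)), phase = "expiratory")
#' m <- lung_mask(array(TRUE, c(2, 2, 2)))
#' classify_prm(insp, expv, m)$pct_fsad  # 100: air trapping everywhere
#' @export
classify_prm <- function(insp, exp_reg, mask, thr = prm_thresholds(),
                         source = "ground-truth") {
  stopifnot(inherits(insp, "ct_volume"), inherits(exp_reg, "ct_volume"),
            inherits(mask, "lung_mask"), inherits(thr, "prm_thresholds"))
  d <- dim(insp$voxels)
  if (!identical(d, dim(exp_reg$voxels)) || !identical(d, dim(mask$voxels)))
    stop("inspiratory, expiratory and mask grids must match")
  m <- mask$voxels
  if (!any(m)) stop("empty lung mask")
  labels <- array(0L, d)
  trapped <- exp_reg$voxels < thr$exp_cut
  low_insp <- insp$voxels < thr$insp_cut
  labels[m & trapped & !low_insp] <- PRM_LABELS[["fSAD"]]
  labels[m & trapped & low_insp] <- PRM_LABELS[["emphysema"]]
  labels[m & !trapped] <- PRM_LABELS[["normal"]]
  map <- prm_map(labels, source = source, spacing = insp$spacing)
  fr <- prm_fractions(map)
  structure(c(list(map = map, n_lung = sum(m)), fr), class = "prm_result")
}

#' @export
print.prm_result <- function(x, ...) {
  cat(sprintf(paste0("<prm_result> %d lung voxels: normal %.2f%%, ",
                     "fSAD %.2f%%, emphysema %.2f%%\n"),
              x$n_lung, x$pct_normal, x$pct_fsad, x$pct_emph))
  invisible(x)
}

#' PRM class volume fractions
#'
#' @param map a [prm_map]; the lung is the set of non-background labels.
#' @return List with `pct_normal`, `pct_fsad`, `pct_emph`, each
#'   100 * class count / lung count.
#' @export
prm_fractions <- function(map) {
  stopifnot(inherits(map, "prm_map"))
  counts <- tabulate(map$labels + 1L, nbins = 4L)
  n <- sum(counts[2:4])
  if (n == 0L) stop("empty lung: no non-background labels")
  list(pct_normal = 100 * counts[2] / n,
       pct_fsad = 100 * counts[3] / n,
       pct_emph = 100 * counts[4] / n)
}

#' Low attenuation area on expiratory CT (LAA-856)
#'
#' Percentage of lung voxels below -856 HU on the expiratory scan, a
#' whole-lung air-trapping index that does not separate emphysematous from
#' small-airway trapping.
#'
#' @param exp expiratory [ct_volume].
#' @param mask [lung_mask].
#' @param cut threshold in HU (default -856).
#' @return Percentage in \[0, 100\].
#' @export
laa856 <- function(exp, mask, cut = -856) {
  stopifnot(inherits(exp, "ct_volume"), inherits(mask, "lung_mask"))
  if (!identical(dim(exp$voxels), dim(mask$voxels))) stop("grid mismatch")
  m <- mask$voxels
  if (!any(m)) stop("empty lung mask")
  100 * sum(exp$voxels[m] < cut) / sum(m)
}

#' Expiratory-to-inspiratory mean lung attenuation ratio (E/I)
#'
#' Mean lung attenuation on the expiratory scan divided by the mean on the
#' inspiratory scan; values nearer 1 indicate more retained gas at
#' expiration.
#'
#' @param exp expiratory [ct_volume].
#' @param insp inspiratory [ct_volume] on the same grid.
#' @param mask [lung_mask].
#' @return Scalar ratio.
#' @export
ei_ratio <- function(exp, insp, mask) {
  stopifnot(inherits(exp, "ct_volume"), inherits(insp, "ct_volume"),
            inherits(mask, "lung_mask"))
  d <- dim(insp$voxels)
  if (!identical(d, dim(exp$voxels)) || !identical(d, dim(mask$voxels)))
    stop("grid mismatch")
  m <- mask$voxels
  if (!any(m)) stop("empty lung mask")
  mi <- mean(insp$voxels[m])
  if (mi == 0) stop("mean inspiratory attenuation is zero")
  mean(exp$voxels[m]) / mi
}
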