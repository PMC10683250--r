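.as_vox <- function(x) {
  if (inherits(x, "ct_volume")) x$voxels else x
}

#' Global structural similarity index (SSIM)
#'
#' Single-window SSIM between two volumes,
#' \deqn{SSIM = \frac{(2\mu_x\mu_z + C_1)(2\sigma_{xz} + C_2)}
#'                   {(\mu_x^2 + \mu_z^2 + C_1)(\sigma_x^2 + \sigma_z^2 + C_2)}}
#' computed from one set of global moments over the (optionally masked)
#' voxels, after normalizing intensities to \[0, 1\] over `data_range`.
#' Variances and the covariance use the population (1/n) normalization.
#'
#' @param x,z volumes ([ct_volume] or numeric arrays) on the same grid.
#' @param C1,C2 stabilizing constants (> 0); defaults (0.01)^2 and (0.03)^2
#'   on the normalized scale.
#' @param data_range length-2 HU interval mapped to \[0, 1\]
#'   (default c(-1024, 600)).
#' @param mask optional [lung_mask] or logical array restricting the voxel
#'   set.
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(x, z, C1 = 0.01^2, C2 = 0.03^2,
                 data_range = c(-1024, 600), mask = NULL) {
  stopifnot(C1 > 0, C2 > 0)
  xv <- .as_vox(x); zv <- .as_vox(z)
  if (!identical(dim(xv), dim(zv))) stop("grid mismatch")
  if (!is.null(mask)) {
    m <- if (inherits(mask, "lung_mask")) mask$voxels else mask
    xv <- xv[m]; zv <- zv[m]
  }
  if (length(xv) < 2L) stop("need at least 2 voxels")
  lo <- data_range[1]; span <- diff(range(data_range))
  xs <- (as.numeric(xv) - lo) / span
  zs <- (as.numeric(zv) - lo) / span
  mx <- mean(xs); mz <- mean(zs)
  vx <- mean((xs - mx)^2); vz <- mean((zs - mz)^2)
  cxz <- mean((xs - mx) * (zs - mz))
  ((2 * mx * mz + C1) * (2 * cxz + C2)) /
    ((mx^2 + mz^2 + C1) * (vx + vz + C2))
}

#' Root mean squared error over a batch of volume pairs
#'
#' RMSE pooled over all scans of a batch and all voxels of each scan:
#' the square root of the mean squared HU difference.
#'
#' @param x,z single volumes or lists of volumes ([ct_volume] or arrays);
#'   paired by position when lists.
#' @param mask optional mask (single, or list matching the batch)
#'   restricting the voxel set of each scan.
#' @return RMSE in HU.
#' @export
rmse <- function(x, z, mask = NULL) {
  xs <- if (is.list(x) && !inherits(x, "ct_volume")) x else list(x)
  zs <- if (is.list(z) && !inherits(z, "ct_volume")) z else list(z)
  if (length(xs) != length(zs)) stop("batch sizes differ")
  if (length(xs) == 0L) stop("empty batch")
  ms <- NULL
  if (!is.null(mask))
    ms <- if (is.list(mask) && !inherits(mask, "lung_mask")) mask
          else rep(list(mask), length(xs))
  ss <- 0; n <- 0
  for (i in seq_along(xs)) {
    a <- .as_vox(xs[[i]]); b <- .as_vox(zs[[i]])
    if (!identical(dim(a), dim(b))) stop("grid mismatch in pair ", i)
    if (!is.null(ms)) {
      m <- if (inherits(ms[[i]], "lung_mask")) ms[[i]]$voxels else ms[[i]]
      a <- a[m]; b <- b[m]
    }
    if (length(a) == 0L) stop("empty voxel set in pair ", i)
    ss <- ss + sum((as.numeric(a) - as.numeric(b))^2)
    n <- n + length(a)
  }
  sqrt(ss / n)
}

#' Dice overlap coefficient for one PRM class
#'
#' `2 |Y_c \eqn{\cap}{n} Yhat_c| / (|Y_c| + |Yhat_c|)`; when the class is
#' absent from both maps the coefficient is 1 by convention.
#'
#' @param y_true,y_pred [prm_map]s (or integer arrays) on the same grid.
#' @param label class label (1 normal, 2 fSAD, 3 emphysema).
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(y_true, y_pred, label) {
  a <- if (inherits(y_true, "prm_map")) y_true$labels else y_true
  b <- if (inherits(y_pred, "prm_map")) y_pred$labels else y_pred
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  ta <- a == label; tb <- b == label
  denom <- sum(ta) + sum(tb)
  if (denom == 0L) return(1.0)
  2 * sum(ta & tb) / denom
}

#' Sample Pearson correlation
#'
#' @param a,b numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Scalar in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
  stats::cor(a, b, method = "pearson")
}
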