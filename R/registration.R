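#' Dense deformation field
#'
#' Voxel displacements defined on the fixed (inspiratory) grid, in voxel
#' units: `warp_volume()` samples the moving volume at `x + u(x)`.
#'
#' @param displacement numeric 4D array `dim x 3`.
#' @param spacing voxel size in mm.
#' @param control_spacing optional B-spline control-point spacing (voxels)
#'   recorded for provenance.
#' @return Object of class `deformation_field`.
#' @export
deformation_field <- function(displacement, spacing = c(1, 1, 1),
                              control_spacing = NULL) {
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement must be a 4D array with 3 components")
  if (anyNA(displacement) || any(!is.finite(displacement)))
    stop("displacement must be finite")
  structure(list(displacement = displacement, spacing = as.numeric(spacing),
                 control_spacing = control_spacing),
            class = "deformation_field")
}

## Sample-point matrix (voxel coordinates) for a grid + displacement.
.sample_points <- function(shape, disp) {
  n <- prod(shape)
  pts <- cbind(
    rep.int(seq_len(shape[1]), shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3]),
    rep(seq_len(shape[3]), each = shape[1] * shape[2]))
  pts + matrix(disp, n, 3)
}

#' Warp a volume by a deformation field
#'
#' Trilinear interpolation of the moving volume at the displaced sample
#' positions; samples falling outside the grid are filled with -1024 HU.
#'
#' @param moving [ct_volume] (or numeric array) to resample.
#' @param field [deformation_field] on the target (fixed) grid.
#' @param fill fill value for out-of-grid samples.
#' @return A [ct_volume] on the fixed grid (or array when `moving` is an
#'   array).
#' @export
warp_volume <- function(moving, field, fill = -1024) {
  stopifnot(inherits(field, "deformation_field"))
  arr <- .as_vox(moving)
  shape <- dim(field$displacement)[1:3]
  pts <- .sample_points(shape, field$displacement)
  out <- array(trilerp_cpp(arr, dim(arr), pts, fill), shape)
  if (inherits(moving, "ct_volume"))
    ct_volume(out, spacing = moving$spacing, origin = moving$origin,
              phase = moving$phase)
  else out
}

## Cubic B-spline basis matrix: rows = voxel positions 1..d, columns =
## control points at spacing `s` voxels (with one margin point per side).
.bspline_basis <- function(d, s) {
  t <- (seq_len(d) - 1) / s
  i <- floor(t)
  u <- t - i
  n <- floor((d - 1) / s) + 4L  # control indices -1 .. n-2
  B <- matrix(0, d, n)
  w <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  for (k in 0:3) {
    col <- i + k  # control index (i-1+k) mapped to 1-based (i-1+k)+2
    B[cbind(seq_len(d), col + 1L)] <- B[cbind(seq_len(d), col + 1L)] + w[, k + 1]
  }
  B
}

## Mode products of a 3D coefficient array with per-axis matrices.
.tensor3 <- function(a, Bx, By, Bz) {
  d <- dim(a)
  m <- Bx %*% matrix(a, d[1], d[2] * d[3])
  a <- array(m, c(nrow(Bx), d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  m <- By %*% matrix(a, d[2], nrow(Bx) * d[3])
  a <- array(m, c(nrow(By), nrow(Bx), d[3]))
  a <- aperm(a, c(3, 2, 1))
  m <- Bz %*% matrix(a, d[3], nrow(Bx) * nrow(By))
  a <- array(m, c(nrow(Bz), nrow(Bx), nrow(By)))
  aperm(a, c(2, 3, 1))
}

## Binary dilation by r steps of the 6-neighbourhood.
.dilate3 <- function(m, r) {
  d <- dim(m)
  sh <- function(a, ax, o) {
    ix <- pmin(pmax(seq_len(d[ax]) + o, 1L), d[ax])
    switch(ax, a[ix, , ], a[, ix, ], a[, , ix])
  }
  for (i in seq_len(r))
    m <- m | sh(m, 1, 1L) | sh(m, 1, -1L) | sh(m, 2, 1L) | sh(m, 2, -1L) |
      sh(m, 3, 1L) | sh(m, 3, -1L)
  m
}

## Discrete 6-neighbour Laplacian with replicated (Neumann) boundaries.
.lap3 <- function(a) {
  d <- dim(a)
  out <- -6 * a
  ix <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  out <- out + a[ix(d[1], 1L), , ] + a[ix(d[1], -1L), , ] +
    a[, ix(d[2], 1L), ] + a[, ix(d[2], -1L), ] +
    a[, , ix(d[3], 1L)] + a[, , ix(d[3], -1L)]
  out
}

#' Free-form deformation registration
#'
#' Multi-resolution B-spline registration of a moving (expiratory) volume
#' onto a fixed (inspiratory) volume by minimizing the masked mean squared
#' HU error with gradient descent on the control-point displacements.  The
#' step size is halved on non-improving steps, so the objective is
#' non-increasing across accepted steps; each level converges when the
#' relative improvement drops below `tol` or its iteration cap is reached.
#'
#' @param fixed fixed [ct_volume] (inspiratory).
#' @param moving moving [ct_volume] (expiratory), same grid shape.
#' @param mask [lung_mask] defining the voxels entering the metric.
#' @param levels number of resolution levels.
#' @param control_spacing control-point spacing in voxels per level,
#'   coarse to fine.
#' @param iters iteration cap per level.
#' @param tol relative-improvement convergence threshold.
#' @param reg_weight bending-energy weight (scalar or one per level):
#'   penalizes the squared discrete Laplacian of the control-point
#'   displacements (HU^2 per squared voxel of curvature).  Suppresses
#'   voxel-scale intensity chasing across the physiological
#'   inspiratory/expiratory density change while leaving smooth
#'   respiratory motion essentially unpenalized.
#' @param mask_dilate dilation (voxels) of the lung mask used as the
#'   metric support, so the lung-body interface anchors the field from
#'   both sides.  The reported MSE uses the undilated mask.
#' @param verbose print per-level objective values.
#' @return A [deformation_field] on the fixed grid (attribute `mse` holds
#'   the initial and final masked MSE).
#' @export
register_ffd <- function(fixed, moving, mask, levels = 3,
                         control_spacing = c(16, 8, 4),
                         iters = rep(40, levels), tol = 1e-4,
                         reg_weight = 1e4, mask_dilate = 3, verbose = FALSE) {
  stopifnot(inherits(fixed, "ct_volume"), inherits(moving, "ct_volume"),
            inherits(mask, "lung_mask"))
  shape <- dim(fixed$voxels)
  if (!identical(shape, dim(moving$voxels))) stop("grid shapes must match")
  if (length(control_spacing) != levels) stop("one control spacing per level")
  if (length(iters) == 1L) iters <- rep(iters, levels)
  if (length(reg_weight) == 1L) reg_weight <- rep(reg_weight, levels)
  m_lung <- as.numeric(mask$voxels)
  m <- if (mask_dilate > 0)
    as.numeric(.dilate3(mask$voxels, mask_dilate)) else m_lung
  nm <- sum(m)
  nm_lung <- sum(m_lung)
  mov <- moving$voxels
  fix <- fixed$voxels
  ## spatial gradient of the moving image (central differences)
  gx <- mov; gy <- mov; gz <- mov
  gx[] <- 0; gy[] <- 0; gz[] <- 0
  gx[2:(shape[1] - 1), , ] <- (mov[3:shape[1], , ] - mov[1:(shape[1] - 2), , ]) / 2
  gy[, 2:(shape[2] - 1), ] <- (mov[, 3:shape[2], ] - mov[, 1:(shape[2] - 2), ]) / 2
  gz[, , 2:(shape[3] - 1)] <- (mov[, , 3:shape[3]] - mov[, , 1:(shape[3] - 2)]) / 2

  u <- array(0, c(shape, 3))
  obj <- function(disp) {
    pts <- .sample_points(shape, disp)
    w <- trilerp_cpp(mov, shape, pts, -1024)
    sum(m * (w - as.numeric(fix))^2) / nm
  }
  obj_lung <- function(disp) {
    pts <- .sample_points(shape, disp)
    w <- trilerp_cpp(mov, shape, pts, -1024)
    sum(m_lung * (w - as.numeric(fix))^2) / nm_lung
  }
  f_init <- obj_lung(u)
  for (lev in seq_len(levels)) {
    s <- control_spacing[lev]
    Bx <- .bspline_basis(shape[1], s)
    By <- .bspline_basis(shape[2], s)
    Bz <- .bspline_basis(shape[3], s)
    nctrl <- c(ncol(Bx), ncol(By), ncol(Bz))
    coef <- array(0, c(nctrl, 3))
    dense <- function(coef) {
      out <- array(0, c(shape, 3))
      for (a in 1:3) out[, , , a] <- .tensor3(coef[, , , a], Bx, By, Bz)
      out
    }
    rw <- reg_weight[lev]
    pen <- function(coef) {
      if (rw <= 0) return(0)
      tot <- 0
      for (a in 1:3) tot <- tot + mean(.lap3(coef[, , , a])^2)
      rw * tot
    }
    f <- obj(u) + pen(coef)
    step <- s / 4  # initial step, voxels of control displacement
    for (it in seq_len(iters[lev])) {
      disp <- u + dense(coef)
      pts <- .sample_points(shape, disp)
      w <- trilerp_cpp(mov, shape, pts, -1024)
      r <- 2 * m * (w - as.numeric(fix)) / nm
      grad <- array(0, c(nctrl, 3))
      for (a in 1:3) {
        ga <- switch(a, trilerp_cpp(gx, shape, pts, 0),
                     trilerp_cpp(gy, shape, pts, 0),
                     trilerp_cpp(gz, shape, pts, 0))
        grad[, , , a] <- .tensor3(array(r * ga, shape), t(Bx), t(By), t(Bz))
        if (rw > 0)
          grad[, , , a] <- grad[, , , a] +
            (2 * rw / prod(nctrl)) * .lap3(.lap3(coef[, , , a]))
      }
      gmax <- max(abs(grad))
      if (!is.finite(gmax)) stop("registration diverged: non-finite gradient")
      if (gmax == 0) break
      accepted <- FALSE
      converged <- FALSE
      for (try in 1:8) {
        cand <- coef - (step / gmax) * grad
        fc <- obj(u + dense(cand)) + pen(cand)
        if (!is.finite(fc)) stop("registration diverged: non-finite objective")
        if (fc < f) {
          rel <- (f - fc) / max(f, .Machine$double.eps)
          coef <- cand
          f <- fc
          step <- step * 1.2
          accepted <- TRUE
          converged <- rel < tol
          break
        }
        step <- step / 2
      }
      if (!accepted || converged) break
    }
    u <- u + dense(coef)
    if (verbose)
      message(sprintf("level %d (spacing %d): masked MSE %.2f", lev, s, f))
  }
  f_final <- obj_lung(u)
  out <- deformation_field(u, spacing = fixed$spacing,
                           control_spacing = control_spacing)
  attr(out, "mse") <- c(initial = f_init, final = f_final)
  out
}
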