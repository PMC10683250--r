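## Minimal neural-network primitives for 3D volumes.
##
## Activations are N x C matrices over a flattened x-fastest voxel grid
## with the grid shape carried alongside.  3^3 convolutions use the
## compiled blocked im2col kernels; weight matrices are (27*Cin) x Cout
## with row layout k + 27*(c_in - 1) over the neighbour offsets
## enumerated by expand.grid(-1:1, -1:1, -1:1).

.nn_cache <- new.env(parent = emptyenv())

## Neighbour index table for a grid shape (0 = zero padding).
.conv_idx <- function(shape) {
  key <- paste0("idx", paste(shape, collapse = "x"))
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  d1 <- shape[1]; d2 <- shape[2]; d3 <- shape[3]
  n <- d1 * d2 * d3
  cx <- rep.int(seq_len(d1), d2 * d3)
  cy <- rep.int(rep(seq_len(d2), each = d1), d3)
  cz <- rep(seq_len(d3), each = d1 * d2)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  idx <- matrix(0L, n, 27L)
  for (k in 1:27) {
    xx <- cx + off[k, 1]; yy <- cy + off[k, 2]; zz <- cz + off[k, 3]
    ok <- xx >= 1L & xx <= d1 & yy >= 1L & yy <= d2 & zz >= 1L & zz <= d3
    v <- (zz - 1L) * (d1 * d2) + (yy - 1L) * d1 + xx
    v[!ok] <- 0L
    idx[, k] <- v
  }
  .nn_cache[[key]] <- idx
  idx
}

## Parent/child maps for 2x pooling (shape must be even).
.pool_maps <- function(shape) {
  key <- paste0("pool", paste(shape, collapse = "x"))
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  hd <- shape %/% 2L
  n_f <- prod(shape)
  cx <- rep.int(seq_len(shape[1]), shape[2] * shape[3])
  cy <- rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3])
  cz <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
  parent <- ((cz + 1L) %/% 2L - 1L) * (hd[1] * hd[2]) +
    ((cy + 1L) %/% 2L - 1L) * hd[1] + (cx + 1L) %/% 2L
  res <- list(parent = parent, hd = hd, n_f = n_f)
  .nn_cache[[key]] <- res
  res
}

conv3_fwd <- function(X, shape, W, b) {
  conv3d_fwd_cpp(X, .conv_idx(shape), W, b)
}

## Input gradient of a 3^3 convolution = convolution of dY with the
## spatially flipped, transposed kernel (exact under zero padding).
conv3_bwd_x <- function(dY, shape, W, Cin, Cout) {
  Wf <- matrix(0, 27L * Cout, Cin)
  for (ci in seq_len(Cin)) for (co in seq_len(Cout))
    Wf[(28L - (1:27)) + 27L * (co - 1L), ci] <- W[(1:27) + 27L * (ci - 1L), co]
  conv3d_fwd_cpp(dY, .conv_idx(shape), Wf, rep(0, Cin))
}

conv3_bwd_w <- function(X, shape, dY) {
  conv3d_gw_cpp(X, .conv_idx(shape), dY)
}

lrelu <- function(Z, alpha = 0.2) {
  Y <- Z
  Y[Z < 0] <- alpha * Z[Z < 0]
  Y
}

lrelu_bwd <- function(dY, Z, alpha = 0.2) {
  dY * ifelse(Z < 0, alpha, 1)
}

pool2_fwd <- function(X, shape) {
  pm <- .pool_maps(shape)
  Y <- rowsum(X, pm$parent) / 8
  list(Y = Y, shape = pm$hd)
}

pool2_bwd <- function(dY, shape) {
  pm <- .pool_maps(shape)
  dY[pm$parent, , drop = FALSE] / 8
}

up2_fwd <- function(X, coarse_shape) {
  fine <- coarse_shape * 2L
  pm <- .pool_maps(fine)
  X[pm$parent, , drop = FALSE]
}

up2_bwd <- function(dY, coarse_shape) {
  fine <- coarse_shape * 2L
  pm <- .pool_maps(fine)
  rowsum(dY, pm$parent)
}

## He-normal initialization for a 3^3 conv.
.init_conv3 <- function(cin, cout, gain = 2) {
  list(W = matrix(stats::rnorm(27 * cin * cout, 0,
                               sqrt(gain / (27 * cin))), 27 * cin, cout),
       b = rep(0, cout))
}

.init_dense <- function(cin, cout, sd = sqrt(2 / max(cin, 1))) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sd), cin, cout),
       b = rep(0, cout))
}

## Adam over a flat named list of parameter lists (each with W and b).
adam_state <- function(par) {
  st <- lapply(par, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                     mb = p$b * 0, vb = p$b * 0))
  attr(st, "t") <- 0L
  st
}

adam_step <- function(par, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  t <- attr(state, "t") + 1L
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    par[[nm]]$W <- par[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    par[[nm]]$b <- par[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  attr(state, "t") <- t
  list(par = par, state = state)
}

## Total parameter count of a flat named parameter list.
.n_params <- function(par) {
  sum(vapply(par, function(p) length(p$W) + length(p$b), numeric(1)))
}
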