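## UNet-like encoder-decoder and patch discriminator: explicit forward and
## backward passes over the flat parameter lists defined in nn.R.
##
## A network with `levels` resolution levels has encoder blocks
## enc1..encL (two 3^3 convolutions each, leaky-ReLU activations,
## 2x average pooling between levels) and decoder blocks dec(L-1)..dec1
## (nearest-neighbour upsampling, skip concatenation, two convolutions).
## Heads are 1x1x1 convolutions on the full-resolution decoder output:
## a main head (intensity or class logits), an optional residual head,
## and an optional threshold MLP fed by the global-average-pooled
## bottleneck.

unet_init <- function(cin, cout, levels = 3, base = 16,
                      residual_head = FALSE, threshold_head = FALSE,
                      mlp_hidden = 16, zero_main_head = FALSE) {
  stopifnot(levels >= 2)
  ch <- base * 2^(seq_len(levels) - 1)
  par <- list()
  for (l in seq_len(levels)) {
    cin_l <- if (l == 1) cin else ch[l - 1]
    par[[paste0("enc", l, ".A")]] <- .init_conv3(cin_l, ch[l])
    par[[paste0("enc", l, ".B")]] <- .init_conv3(ch[l], ch[l])
  }
  for (l in seq_len(levels - 1)) {
    par[[paste0("dec", l, ".A")]] <- .init_conv3(ch[l + 1] + ch[l], ch[l])
    par[[paste0("dec", l, ".B")]] <- .init_conv3(ch[l], ch[l])
  }
  par$head <- .init_dense(ch[1], cout, sd = sqrt(1 / ch[1]))
  if (zero_main_head) par$head$W[] <- 0
  if (residual_head) par$res <- .init_dense(ch[1], 1, sd = sqrt(1 / ch[1]))
  if (threshold_head) {
    par$thr1 <- .init_dense(ch[levels], mlp_hidden)
    par$thr2 <- .init_dense(mlp_hidden, 1, sd = 0)  # zero-init: offset 0
  }
  attr(par, "arch") <- list(cin = cin, cout = cout, levels = levels,
                            base = base, ch = ch,
                            residual_head = residual_head,
                            threshold_head = threshold_head)
  par
}

unet_fwd <- function(par, X, shape) {
  a <- attr(par, "arch")
  L <- a$levels
  shapes <- vector("list", L)
  shapes[[1]] <- as.integer(shape)
  for (l in 2:L) shapes[[l]] <- shapes[[l - 1]] %/% 2L
  enc <- vector("list", L)
  cur <- X
  for (l in seq_len(L)) {
    inp <- if (l == 1) cur else pool2_fwd(cur, shapes[[l - 1]])$Y
    Z1 <- conv3_fwd(inp, shapes[[l]], par[[paste0("enc", l, ".A")]]$W,
                    par[[paste0("enc", l, ".A")]]$b)
    A1 <- lrelu(Z1)
    Z2 <- conv3_fwd(A1, shapes[[l]], par[[paste0("enc", l, ".B")]]$W,
                    par[[paste0("enc", l, ".B")]]$b)
    A2 <- lrelu(Z2)
    enc[[l]] <- list(inp = inp, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
    cur <- A2
  }
  dec <- vector("list", max(L - 1, 0))
  for (l in rev(seq_len(L - 1))) {
    up <- up2_fwd(cur, shapes[[l + 1]])
    cat_ <- cbind(up, enc[[l]]$A2)
    Z1 <- conv3_fwd(cat_, shapes[[l]], par[[paste0("dec", l, ".A")]]$W,
                    par[[paste0("dec", l, ".A")]]$b)
    A1 <- lrelu(Z1)
    Z2 <- conv3_fwd(A1, shapes[[l]], par[[paste0("dec", l, ".B")]]$W,
                    par[[paste0("dec", l, ".B")]]$b)
    A2 <- lrelu(Z2)
    dec[[l]] <- list(cat = cat_, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
    cur <- A2
  }
  out <- sweep(cur %*% par$head$W, 2, par$head$b, `+`)
  res <- NULL
  if (a$residual_head)
    res <- sweep(cur %*% par$res$W, 2, par$res$b, `+`)
  thr <- NULL
  if (a$threshold_head) {
    gap <- matrix(colMeans(enc[[L]]$A2), 1)
    Zm <- gap %*% par$thr1$W + matrix(par$thr1$b, 1)
    Am <- lrelu(Zm)
    toff <- drop(Am %*% par$thr2$W + par$thr2$b)
    thr <- list(gap = gap, Zm = Zm, Am = Am, toff = toff)
  }
  list(out = out, res = res, thr = thr,
       cache = list(enc = enc, dec = dec, shapes = shapes, feat = cur))
}

## dOut: gradient at the main head output; dRes at the residual head;
## dT at the threshold offset.  Returns the gradient list (and the input
## gradient when want_dx).
unet_bwd <- function(par, fwd, dOut, dRes = NULL, dT = NULL,
                     want_dx = FALSE) {
  a <- attr(par, "arch")
  L <- a$levels
  ch <- a$ch
  enc <- fwd$cache$enc; dec <- fwd$cache$dec; shapes <- fwd$cache$shapes
  g <- list()
  feat <- fwd$cache$feat
  g$head <- list(W = crossprod(feat, dOut), b = colSums(dOut))
  dfeat <- dOut %*% t(par$head$W)
  if (!is.null(dRes) && a$residual_head) {
    g$res <- list(W = crossprod(feat, dRes), b = colSums(dRes))
    dfeat <- dfeat + dRes %*% t(par$res$W)
  } else if (a$residual_head) {
    g$res <- list(W = par$res$W * 0, b = par$res$b * 0)
  }
  dbottle_thr <- NULL
  if (a$threshold_head) {
    if (!is.null(dT) && dT != 0) {
      th <- fwd$thr
      g$thr2 <- list(W = t(th$Am) * dT, b = dT)
      dAm <- dT * t(par$thr2$W)
      dZm <- lrelu_bwd(dAm, th$Zm)
      g$thr1 <- list(W = crossprod(th$gap, dZm), b = drop(dZm))
      dgap <- dZm %*% t(par$thr1$W)  # 1 x ch[L]
      nL <- nrow(enc[[L]]$A2)
      dbottle_thr <- matrix(dgap, nL, ch[L], byrow = TRUE) / nL
    } else {
      g$thr1 <- list(W = par$thr1$W * 0, b = par$thr1$b * 0)
      g$thr2 <- list(W = par$thr2$W * 0, b = par$thr2$b * 0)
    }
  }
  ## decoder chain, fine to coarse
  dskip <- vector("list", L)
  dcur <- dfeat
  for (l in seq_len(L - 1)) {
    dc <- dec[[l]]
    dZ2 <- lrelu_bwd(dcur, dc$Z2)
    nmB <- paste0("dec", l, ".B")
    g[[nmB]] <- list(W = conv3_bwd_w(dc$A1, shapes[[l]], dZ2),
                     b = colSums(dZ2))
    dA1 <- conv3_bwd_x(dZ2, shapes[[l]], par[[nmB]]$W, ch[l], ch[l])
    dZ1 <- lrelu_bwd(dA1, dc$Z1)
    nmA <- paste0("dec", l, ".A")
    g[[nmA]] <- list(W = conv3_bwd_w(dc$cat, shapes[[l]], dZ1),
                     b = colSums(dZ1))
    dcat <- conv3_bwd_x(dZ1, shapes[[l]], par[[nmA]]$W,
                        ch[l + 1] + ch[l], ch[l])
    dup <- dcat[, seq_len(ch[l + 1]), drop = FALSE]
    dskip[[l]] <- dcat[, ch[l + 1] + seq_len(ch[l]), drop = FALSE]
    dcur <- up2_bwd(dup, shapes[[l + 1]])
  }
  ## encoder chain, coarse to fine
  dA2 <- dcur  # gradient at bottleneck output
  if (!is.null(dbottle_thr)) dA2 <- dA2 + dbottle_thr
  dX <- NULL
  for (l in rev(seq_len(L))) {
    if (l < L) dA2 <- dA2 + dskip[[l]]
    ec <- enc[[l]]
    dZ2 <- lrelu_bwd(dA2, ec$Z2)
    nmB <- paste0("enc", l, ".B")
    g[[nmB]] <- list(W = conv3_bwd_w(ec$A1, shapes[[l]], dZ2),
                     b = colSums(dZ2))
    dA1 <- conv3_bwd_x(dZ2, shapes[[l]], par[[nmB]]$W, ch[l], ch[l])
    dZ1 <- lrelu_bwd(dA1, ec$Z1)
    nmA <- paste0("enc", l, ".A")
    cin_l <- if (l == 1) a$cin else ch[l - 1]
    g[[nmA]] <- list(W = conv3_bwd_w(ec$inp, shapes[[l]], dZ1),
                     b = colSums(dZ1))
    if (l > 1) {
      dinp <- conv3_bwd_x(dZ1, shapes[[l]], par[[nmA]]$W, cin_l, ch[l])
      dA2 <- pool2_bwd(dinp, shapes[[l - 1]])
    } else if (want_dx) {
      dX <- conv3_bwd_x(dZ1, shapes[[1]], par[[nmA]]$W, cin_l, ch[1])
    }
  }
  list(grads = g, dX = dX)
}

## Patch discriminator: two strided (conv + pool) stages then a 1x1x1
## scoring head; returns per-patch logits on the quarter-resolution grid.
disc_init <- function(cin, base = 16) {
  par <- list(c1 = .init_conv3(cin, base),
              c2 = .init_conv3(base, 2 * base),
              head = .init_dense(2 * base, 1, sd = sqrt(1 / (2 * base))))
  attr(par, "arch") <- list(cin = cin, base = base)
  par
}

disc_fwd <- function(par, X, shape) {
  a <- attr(par, "arch")
  Z1 <- conv3_fwd(X, shape, par$c1$W, par$c1$b)
  A1 <- lrelu(Z1)
  P1 <- pool2_fwd(A1, shape)
  Z2 <- conv3_fwd(P1$Y, P1$shape, par$c2$W, par$c2$b)
  A2 <- lrelu(Z2)
  P2 <- pool2_fwd(A2, P1$shape)
  out <- sweep(P2$Y %*% par$head$W, 2, par$head$b, `+`)
  list(out = out,
       cache = list(X = X, shape = shape, Z1 = Z1, P1Y = P1$Y, s1 = P1$shape,
                    Z2 = Z2, s2 = P2$shape, feat = P2$Y))
}

disc_bwd <- function(par, fwd, dOut, want_dx = FALSE) {
  a <- attr(par, "arch")
  cc <- fwd$cache
  g <- list()
  g$head <- list(W = crossprod(cc$feat, dOut), b = colSums(dOut))
  dP2 <- dOut %*% t(par$head$W)
  dA2 <- pool2_bwd(dP2, cc$s1)
  dZ2 <- lrelu_bwd(dA2, cc$Z2)
  g$c2 <- list(W = conv3_bwd_w(cc$P1Y, cc$s1, dZ2), b = colSums(dZ2))
  dP1 <- conv3_bwd_x(dZ2, cc$s1, par$c2$W, a$base, 2 * a$base)
  dA1 <- pool2_bwd(dP1, cc$shape)
  dZ1 <- lrelu_bwd(dA1, cc$Z1)
  g$c1 <- list(W = conv3_bwd_w(cc$X, cc$shape, dZ1), b = colSums(dZ1))
  dX <- NULL
  if (want_dx)
    dX <- conv3_bwd_x(dZ1, cc$shape, par$c1$W, a$cin, a$base)
  list(grads = g, dX = dX)
}
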