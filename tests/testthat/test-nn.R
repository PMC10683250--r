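## Internal network machinery: adjoint/gradient correctness is the load-
## bearing property behind every training result.

test_that("convolution input-gradient is the exact adjoint of the forward", {
  set.seed(1)
  shape <- c(5L, 4L, 3L)
  n <- prod(shape)
  cin <- 2L; cout <- 3L
  W <- matrix(stats::rnorm(27 * cin * cout), 27 * cin, cout)
  X <- matrix(stats::rnorm(n * cin), n, cin)
  Y <- matrix(stats::rnorm(n * cout), n, cout)
  ## <conv(X), Y> == <X, conv_adjoint(Y)>
  lhs <- sum(lungprm:::conv3_fwd(X, shape, W, rep(0, cout)) * Y)
  rhs <- sum(X * lungprm:::conv3_bwd_x(Y, shape, W, cin, cout))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  ## pooling and upsampling are mutual adjoints (up to the 1/8 factor)
  shape2 <- c(4L, 4L, 2L)
  A <- matrix(stats::rnorm(prod(shape2) * 2), prod(shape2), 2)
  Bc <- matrix(stats::rnorm(prod(shape2 %/% 2L) * 2), prod(shape2 %/% 2L), 2)
  lhs <- sum(lungprm:::pool2_fwd(A, shape2)$Y * Bc)
  rhs <- sum(A * lungprm:::pool2_bwd(Bc, shape2))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  lhs <- sum(lungprm:::up2_fwd(Bc, shape2 %/% 2L) * A)
  rhs <- sum(Bc * lungprm:::up2_bwd(A, shape2 %/% 2L))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("UNet backward matches finite differences", {
  set.seed(2)
  shape <- c(8L, 8L, 8L); n <- prod(shape)
  par <- lungprm:::unet_init(2, 3, levels = 2, base = 2,
                             residual_head = TRUE, threshold_head = TRUE,
                             mlp_hidden = 4)
  par$thr2$W[] <- stats::rnorm(length(par$thr2$W), 0, 0.1)
  X <- matrix(stats::rnorm(n * 2), n, 2)
  a_out <- matrix(stats::rnorm(n * 3), n, 3)
  a_res <- matrix(stats::rnorm(n), n, 1)
  a_t <- 0.7
  loss <- function(p) {
    f <- lungprm:::unet_fwd(p, X, shape)
    sum(f$out * a_out) + sum(f$res * a_res) + a_t * f$thr$toff
  }
  f0 <- lungprm:::unet_fwd(par, X, shape)
  bw <- lungprm:::unet_bwd(par, f0, a_out, dRes = a_res, dT = a_t)
  eps <- 1e-6
  set.seed(3)
  for (nm in c("enc1.A", "enc2.B", "dec1.A", "head", "res", "thr1", "thr2")) {
    g <- bw$grads[[nm]]$W
    i <- sample(length(g), 1)
    p2 <- par; p2[[nm]]$W[i] <- p2[[nm]]$W[i] + eps
    num <- (loss(p2) - loss(par)) / eps
    expect_equal(g[i], num, tolerance = 1e-3)
  }
})

test_that("network builds are deterministic and shaped as declared", {
  cfg <- net_config(unet_depth = 2, base_channels = 2, patch_size = 8)
  set.seed(5); a <- build_networks(cfg)
  set.seed(5); b <- build_networks(cfg)
  expect_identical(lungprm:::.n_params(a$prm), lungprm:::.n_params(b$prm))
  expect_identical(a$g1, b$g1)
  ## smoke forward on a zero patch: finite, declared shapes
  n <- 8^3
  f1 <- lungprm:::unet_fwd(a$g1, matrix(0, n, 1), rep(8L, 3))
  expect_equal(dim(f1$out), c(n, 1L))
  expect_true(all(is.finite(f1$out)))
  fp <- lungprm:::unet_fwd(a$prm, matrix(0, n, 2), rep(8L, 3))
  expect_equal(dim(fp$out), c(n, 3L))
  expect_equal(dim(fp$res), c(n, 1L))
  expect_true(is.finite(fp$thr$toff))
  ## refiner reproduces its conditioning input at initialization
  X <- matrix(stats::rnorm(n), n, 1)
  fake1 <- X + lungprm:::unet_fwd(a$g1, X, rep(8L, 3))$out
  f2 <- lungprm:::unet_fwd(a$g2, cbind(X, fake1), rep(8L, 3))
  expect_equal(fake1 + f2$out, fake1, tolerance = 1e-12)
  ## incompatible patch/stride is rejected
  expect_error(net_config(unet_depth = 3, patch_size = 50), "stride")
})
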