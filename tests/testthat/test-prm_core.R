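mkvol <- function(vals, phase = "inspiratory") {
  n <- length(vals)
  ct_volume(array(vals, c(n, 1, 1)), phase = phase)
}
mkmask <- function(n) lung_mask(array(TRUE, c(n, 1, 1)))

test_that("the PRM rule classifies the canonical voxel cases", {
  insp <- mkvol(c(-900, -975, -900, -975, -950))
  expv <- mkvol(c(-900, -960, -700, -800, -900), phase = "expiratory")
  res <- classify_prm(insp, expv, mkmask(5))
  ## fSAD, emphysema, normal, normal ("all other regions"), and the
  ## boundary convention: insp exactly -950 takes the fSAD branch
  expect_equal(as.integer(res$map$labels), c(2L, 3L, 1L, 1L, 2L))
  ## expiratory exactly -856 is not trapped
  res2 <- classify_prm(mkvol(-900), mkvol(-856, phase = "expiratory"),
                       mkmask(1))
  expect_equal(as.integer(res2$map$labels), 1L)
})

test_that("classification matches the brute-force rule oracle exactly", {
  g <- hu_grid_pair()
  n <- length(g$insp)
  d <- c(n, 1, 1)
  insp <- ct_volume(array(g$insp, d))
  expv <- ct_volume(array(g$exp, d), phase = "expiratory")
  res <- classify_prm(insp, expv, lung_mask(array(TRUE, d)))
  oracle <- oracle_prm_map(array(g$insp, d), array(g$exp, d),
                           array(TRUE, d))
  expect_identical(res$map$labels, oracle)
  ## and on random volumes with non-trivial masks
  set.seed(11)
  for (rep in 1:5) {
    d <- c(12, 12, 12)
    iv <- array(stats::rnorm(prod(d), -880, 80), d)
    ev <- array(stats::rnorm(prod(d), -850, 80), d)
    lung <- array(stats::runif(prod(d)) < 0.7, d)
    if (!any(lung)) next
    res <- classify_prm(ct_volume(iv), ct_volume(ev, phase = "expiratory"),
                        lung_mask(lung))
    expect_identical(res$map$labels,
                     oracle_prm_map(pmax(iv, -1024), pmax(ev, -1024), lung))
  }
})

test_that("class fractions are exact and conserve to 100 percent", {
  labs <- array(c(1L, 1L, 2L, 3L), c(4, 1, 1))
  fr <- prm_fractions(prm_map(labs))
  expect_equal(unlist(fr), c(pct_normal = 50, pct_fsad = 25, pct_emph = 25))
  fr2 <- prm_fractions(prm_map(array(1L, c(3, 3, 3))))
  expect_equal(fr2$pct_normal, 100)
  set.seed(2)
  for (rep in 1:50) {
    labs <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
    if (!any(labs > 0)) labs[1] <- 1L
    fr <- prm_fractions(prm_map(labs))
    expect_lt(abs(fr$pct_normal + fr$pct_fsad + fr$pct_emph - 100), 1e-9)
  }
  expect_error(prm_fractions(prm_map(array(0L, c(2, 2, 2)))), "empty lung")
})

test_that("raising the expiratory cut only grows the trapped voxel set", {
  set.seed(3)
  d <- c(10, 10, 10)
  iv <- ct_volume(array(stats::rnorm(prod(d), -900, 60), d))
  ev <- ct_volume(array(stats::rnorm(prod(d), -850, 60), d),
                  phase = "expiratory")
  m <- lung_mask(array(TRUE, d))
  prev <- -Inf
  for (cut in c(-900, -856, -800, -750)) {
    res <- classify_prm(iv, ev, m, prm_thresholds(-950, cut))
    trapped <- sum(res$map$labels %in% c(2L, 3L))
    expect_gte(trapped, prev)
    prev <- trapped
  }
})

test_that("LAA-856 counts trapped expiratory voxels", {
  m <- mkmask(4)
  expect_equal(laa856(mkvol(rep(-900, 4), "expiratory"), m), 100)
  expect_equal(laa856(mkvol(rep(-700, 4), "expiratory"), m), 0)
  expect_equal(laa856(mkvol(c(-900, -900, -700, -700), "expiratory"), m), 50)
  expect_error(laa856(mkvol(rep(-900, 4), "expiratory"),
                      lung_mask(array(c(TRUE, rep(FALSE, 3)), c(4, 1, 1)))),
               NA)  # single-voxel lung is fine
})

test_that("E/I ratio follows its printed definition", {
  m <- mkmask(4)
  v <- mkvol(rep(-880, 4))
  expect_equal(ei_ratio(v, v, m), 1.0)
  e <- mkvol(rep(-800, 4), "expiratory")
  i <- mkvol(rep(-880, 4))
  expect_equal(ei_ratio(e, i, m), -800 / -880)
  ## raising expiratory HU toward zero strictly decreases E/I
  e2 <- mkvol(rep(-750, 4), "expiratory")
  expect_lt(ei_ratio(e2, i, m), ei_ratio(e, i, m))
  zi <- mkvol(rep(0, 4))
  expect_error(ei_ratio(e, zi, m), "zero")
})

test_that("grid and mask contracts are enforced", {
  expect_error(classify_prm(mkvol(-900), mkvol(c(-900, -900)), mkmask(1)),
               "match")
  expect_error(prm_thresholds(-856, -950), "below")
  d <- c(2, 2, 2)
  expect_error(classify_prm(ct_volume(array(-900, d)),
                            ct_volume(array(-900, d)),
                            structure(list(voxels = array(FALSE, d),
                                           spacing = c(1, 1, 1)),
                                      class = "lung_mask")),
               "empty")
})
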