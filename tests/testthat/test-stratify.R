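## Exhaustive pair-counting AUC (Mann-Whitney with ties counted 1/2).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("fSAD binarization uses the strict group rule", {
  expect_identical(binarize_fsad(c(10, 15, 20), 15), c(0L, 0L, 1L))
  expect_identical(binarize_fsad(c(5, 50, 99.9), 0), c(1L, 1L, 1L))
  ## a 10-30% sweep yields one labelling per threshold, monotone in count
  v <- c(12, 18, 22, 27, 31) * 100 / 100
  v <- pmin(v, 100)
  prev <- Inf
  for (th in seq(10, 30, by = 5)) {
    lab <- binarize_fsad(v, th)
    expect_length(lab, 5)
    expect_lte(sum(lab), prev)
    prev <- sum(lab)
  }
  expect_error(binarize_fsad(c(10, 20), 120), "threshold")
  expect_error(binarize_fsad(c(10, 200), 15), "values")
})

test_that("AUC equals exhaustive pair counting and its limit identities", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(4, 8), rep(0:1, 4))$auc, 0.5)
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    sc <- sample(1:8, n, replace = TRUE)  # ties likely
    lab <- sample(0:1, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(sc, lab)$auc, auc_pairs(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC invariances hold", {
  set.seed(9)
  sc <- stats::rnorm(30); lab <- rep(0:1, 15)
  a <- roc_auc(sc, lab)$auc
  ## strictly monotone transform of the scores
  expect_equal(roc_auc(exp(2 * sc) + 1, lab)$auc, a, tolerance = 1e-12)
  ## swapping the labels mirrors the AUC
  expect_equal(roc_auc(sc, 1 - lab)$auc, 1 - a, tolerance = 1e-12)
})

test_that("Youden cut-off maximizes sensitivity + specificity - 1", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_gt(r$cutoff, 2); expect_lt(r$cutoff, 3)
  expect_equal(r$sens_at_cutoff, 1.0)
  expect_equal(r$spec_at_cutoff, 1.0)
  ## reported operating point is consistent with a direct confusion matrix
  set.seed(10)
  sc <- stats::rnorm(60)
  lab <- as.integer(sc + stats::rnorm(60) > 0)
  r2 <- roc_auc(sc, lab)
  pred <- as.integer(sc > r2$cutoff)
  expect_equal(r2$sens_at_cutoff, sum(pred == 1 & lab == 1) / sum(lab == 1),
               tolerance = 1e-12)
  expect_equal(r2$spec_at_cutoff, sum(pred == 0 & lab == 0) / sum(lab == 0),
               tolerance = 1e-12)
  ## labels independent of scores: J near zero on a large sample
  set.seed(11)
  sc <- stats::rnorm(1000); lab <- sample(0:1, 1000, replace = TRUE)
  r3 <- roc_auc(sc, lab)
  expect_lt(r3$sens_at_cutoff + r3$spec_at_cutoff - 1, 0.12)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(12)
  tbl <- data.frame(gt_fsad = stats::rnorm(10, 20, 5),
                    pred_fsad = stats::rnorm(10, 20, 5),
                    gt_emph = stats::rnorm(10, 5, 2))
  cm <- correlation_matrix(tbl)
  expect_equal(diag(cm), c(gt_fsad = 1, pred_fsad = 1, gt_emph = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["gt_fsad", "pred_fsad"],
               pearson_r(tbl$gt_fsad, tbl$pred_fsad))
  tbl$flat <- 1
  expect_error(correlation_matrix(tbl), "zero-variance")
  expect_error(correlation_matrix(tbl[1:2, 1:3]), "3 subjects")
})
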