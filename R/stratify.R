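#' Binarize PRM fSAD percentages for SAD stratification
#'
#' Group label 1 means the fSAD volume percentage strictly exceeds the
#' threshold (subjects with significant small airway disease).
#'
#' @param values fSAD percentages in \[0, 100\].
#' @param threshold percentage threshold in \[0, 100\].
#' @return Integer vector of 0/1 labels.
#' @export
binarize_fsad <- function(values, threshold) {
  if (threshold < 0 || threshold > 100) stop("threshold must be in [0, 100]")
  if (any(values < 0 | values > 100)) stop("values must be in [0, 100]")
  as.integer(values > threshold)
}

#' ROC curve and AUC of predicted fSAD percentages
#'
#' ROC over all distinct score thresholds with trapezoidal AUC (equal to
#' the Mann-Whitney U statistic normalized by n1*n0, ties counted 1/2),
#' plus the Youden-optimal operating point.
#'
#' @param scores predicted fSAD percentages (or any scores).
#' @param labels binary reference labels; both classes must be present.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `cutoff`, `sens_at_cutoff`, `spec_at_cutoff`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 direction = "<", levels = c(0, 1), quiet = TRUE)
  res <- structure(list(thresholds = r$thresholds,
                        sensitivity = r$sensitivities,
                        specificity = r$specificities,
                        auc = as.numeric(r$auc)),
                   class = "roc_result")
  yc <- youden_cutoff(res)
  res$cutoff <- yc$cutoff
  res$sens_at_cutoff <- yc$sensitivity
  res$spec_at_cutoff <- yc$specificity
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f, cutoff %.3g (sens %.3f, spec %.3f)\n",
              x$auc, x$cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' Youden-optimal cut-off of a ROC curve
#'
#' Threshold maximizing Youden's J = sensitivity + specificity - 1; ties
#' resolve to the lower threshold.
#'
#' @param roc a `roc_result`.
#' @return List `cutoff`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  cand <- which(is.finite(roc$thresholds))
  if (length(cand) == 0L) cand <- seq_along(j)
  best <- cand[j[cand] >= max(j[cand]) - 1e-12]
  pick <- best[which.min(roc$thresholds[best])]
  list(cutoff = roc$thresholds[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick])
}

#' Pairwise Pearson correlation matrix of PRM metrics
#'
#' @param metrics data frame or matrix, one row per subject, columns the
#'   PRM volume percentages from the compared sources.
#' @return Symmetric correlation matrix.
#' @export
correlation_matrix <- function(metrics) {
  m <- as.matrix(metrics)
  if (nrow(m) < 3L) stop("need at least 3 subjects")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance column: ",
                          paste(colnames(m)[sds == 0], collapse = ", "))
  stats::cor(m, method = "pearson")
}
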