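#' ROC analysis with Youden-index optimal cut-off
#'
#' Empirical ROC by sweeping a threshold over the observed feature
#' values (predicting positive when `feature >= cut-off`). The AUC is
#' the trapezoid area, which equals the normalized Mann-Whitney U
#' statistic; its standard error uses the Hanley-McNeil formula. The
#' optimal cut-off maximizes Youden's J = sensitivity + specificity - 1,
#' with ties broken toward higher specificity (the larger cut-off).
#'
#' @param feature numeric feature values.
#' @param positive logical class labels (e.g. recovery above the median).
#' @return a `roc_result`: list `auc`, `standard_error`, `sensitivity`,
#'   `one_minus_specificity`, `cut_off`, `youden_j`, `n_pos`, `n_neg`,
#'   and the full `curve` data.frame (`cut_off`, `tpr`, `fpr`).
#' @export
roc_analysis <- function(feature, positive) {
  stopifnot(length(feature) == length(positive))
  ok <- stats::complete.cases(feature, positive)
  feature <- feature[ok]; positive <- as.logical(positive[ok])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")

  thr <- sort(unique(feature), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(feature[positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(feature[!positive] >= t), numeric(1))
  curve <- data.frame(cut_off = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))

  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))

  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]     # higher specificity on ties
  out <- list(auc = auc, standard_error = se,
              sensitivity = tpr[best], one_minus_specificity = fpr[best],
              cut_off = thr[best], youden_j = j[best],
              n_pos = n1, n_neg = n0, curve = curve)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (SE %.3f), cut-off %.4g, sens %.3f, 1-spec %.3f>\n",
              x$auc, x$standard_error, x$cut_off, x$sensitivity,
              x$one_minus_specificity))
  invisible(x)
}
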