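check_preds <- function(preds, require_both = TRUE) {
  if (!is.data.frame(preds) || !all(c("truth", "prob") %in% names(preds))) {
    abort("`preds` must be a data frame with `truth` (0/1) and `prob` columns",
          class = "fallrisk_error_validation")
  }
  if (any(!preds$truth %in% c(0, 1))) {
    abort("`truth` must be 0/1", class = "fallrisk_error_validation")
  }
  if (any(!is.finite(preds$prob)) || any(preds$prob < 0 | preds$prob > 1)) {
    abort("`prob` must be finite probabilities in [0, 1]",
          class = "fallrisk_error_validation")
  }
  if (require_both && length(unique(preds$truth)) != 2) {
    abort("both classes must be present", class = "fallrisk_error_single_class")
  }
  invisible(preds)
}

midranks <- function(x) rank(x, ties.method = "average")

#' ROC AUC with a DeLong confidence interval
#'
#' The area under the ROC curve is the Mann-Whitney statistic (ties counted
#' 1/2); its variance is estimated by the DeLong structural-components
#' method, from which a normal-theory 95% confidence interval is formed and
#' truncated to `[0, 1]`.
#'
#' @param preds Data frame with `truth` (0/1) and `prob` columns, e.g. the
#'   prediction set of [nested_cv_evaluate()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `se`.
#' @export
roc_auc_delong <- function(preds, conf_level = 0.95) {
  check_preds(preds)
  x <- preds$prob[preds$truth == 1]   # events
  y <- preds$prob[preds$truth == 0]   # nonevents
  m <- length(x); n <- length(y)
  tz <- midranks(c(x, y))
  tx <- midranks(x)
  ty <- midranks(y)
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (tz[seq_len(m)] - tx) / n            # event components
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m    # nonevent components
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(auc = auc,
         ci_low = max(0, auc - z * se),
         ci_high = min(1, auc + z * se),
         se = se)
}

#' Youden-index operating cutoff
#'
#' The probability cutoff maximizing the Youden index J = sensitivity +
#' specificity - 1, evaluated at the midpoints of adjacent distinct
#' predicted probabilities (classification rule: prob >= cutoff is
#' positive). Ties in J are broken toward the lower cutoff, i.e. toward
#' higher sensitivity.
#'
#' @inheritParams roc_auc_delong
#' @return The cutoff, with attributes `youden_j` (the maximized J) and
#'   `degenerate` (`TRUE` when all probabilities are equal, in which case
#'   J = 0 and the common value is returned).
#' @export
youden_cutoff <- function(preds) {
  check_preds(preds)
  u <- sort(unique(preds$prob))
  if (length(u) == 1) {
    return(structure(u, youden_j = 0, degenerate = TRUE))
  }
  cand <- (u[-length(u)] + u[-1]) / 2
  pos <- preds$truth == 1
  j <- vapply(cand, function(ct) {
    mean(preds$prob[pos] >= ct) + mean(preds$prob[!pos] < ct) - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]  # lowest cutoff among ties
  structure(cand[best], youden_j = j[best], degenerate = FALSE)
}

#' Confusion-matrix metrics at a probability cutoff
#'
#' Sensitivity, specificity, positive predictive value and the Matthews
#' correlation coefficient of the rule prob >= cutoff. MCC =
#' (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0 when
#' any factor of the denominator is 0.
#'
#' @inheritParams roc_auc_delong
#' @param cutoff Finite probability cutoff.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `mcc`,
#'   `tp`, `fp`, `tn`, `fn`, `cutoff`.
#' @export
classification_metrics <- function(preds, cutoff) {
  check_preds(preds, require_both = FALSE)
  if (!is.finite(cutoff)) {
    abort("`cutoff` must be finite", class = "fallrisk_error_validation")
  }
  pred_pos <- preds$prob >= cutoff
  tp <- sum(pred_pos & preds$truth == 1)
  fp <- sum(pred_pos & preds$truth == 0)
  fn <- sum(!pred_pos & preds$truth == 1)
  tn <- sum(!pred_pos & preds$truth == 0)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
         ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn, cutoff = as.numeric(cutoff))
}

#' Average precision (area under the precision-recall step curve)
#'
#' Mean precision summarised as the step-wise area under the
#' precision-recall curve: the sum over descending probability thresholds of
#' the recall increment times the precision at that threshold.
#'
#' @inheritParams roc_auc_delong
#' @return Average precision in `[0, 1]`.
#' @export
mean_precision <- function(preds) {
  check_preds(preds)
  thr <- sort(unique(preds$prob), decreasing = TRUE)
  n_pos <- sum(preds$truth == 1)
  prev_recall <- 0
  ap <- 0
  for (v in thr) {
    sel <- preds$prob >= v
    tp <- sum(sel & preds$truth == 1)
    recall <- tp / n_pos
    precision <- tp / sum(sel)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Full discrimination report for a prediction set
#'
#' Bundles the AUC with DeLong CI, average precision, and the Youden-cutoff
#' operating characteristics into a single one-row performance report.
#'
#' @inheritParams roc_auc_delong
#' @return One-row tibble: `roc_auc`, `ci_low`, `ci_high`,
#'   `mean_precision`, `cutoff`, `sensitivity`, `specificity`,
#'   `ppv_at_cutoff`, `mcc`.
#' @export
performance_report <- function(preds) {
  d <- roc_auc_delong(preds)
  ct <- youden_cutoff(preds)
  cm <- classification_metrics(preds, as.numeric(ct))
  tibble(roc_auc = d$auc, ci_low = d$ci_low, ci_high = d$ci_high,
         mean_precision = mean_precision(preds),
         cutoff = as.numeric(ct),
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         ppv_at_cutoff = cm$ppv, mcc = cm$mcc)
}
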