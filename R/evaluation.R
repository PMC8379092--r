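# Classifier evaluation: confusion metrics, ROC/AUC, and McNemar's paired
# test on discordant correct/incorrect classifications of two classifiers.

#' Confusion-matrix metrics
#'
#' Counts true/false positives and negatives (positive class = 1, vMCI) and
#' reports accuracy, sensitivity and specificity as percentages to two
#' decimals.
#'
#' @param predicted,truth Equal-length 0/1 label vectors; the truth must
#'   contain both classes.
#' @return A list of class `confusion_metrics`: `TP`, `FN`, `TN`, `FP`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' m <- confusion_metrics(rep(c(1, 0, 1, 0), c(57, 17, 14, 25)),
#'                        rep(c(1, 0), c(74, 39)))
#' m$accuracy  # 72.57
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0L) stop("empty input")
  if (length(unique(truth)) < 2) stop("truth must contain both classes")
  stopifnot(all(predicted %in% c(0, 1)), all(truth %in% c(0, 1)))
  TP <- sum(predicted == 1 & truth == 1)
  FN <- sum(predicted == 0 & truth == 1)
  TN <- sum(predicted == 0 & truth == 0)
  FP <- sum(predicted == 1 & truth == 0)
  structure(list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    accuracy = round(100 * (TP + TN) / (TP + FN + TN + FP), 2),
    sensitivity = round(100 * TP / (TP + FN), 2),
    specificity = round(100 * TN / (TN + FP), 2)
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Accuracy %.2f%%  Sensitivity %.2f%%  Specificity %.2f%%  (TP %d, FN %d, TN %d, FP %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique score values, anchoring the
#' curve at (0,0) and (1,1), and computes the area under the curve by the
#' trapezoidal rule. With tied scores the trapezoid contributes the diagonal
#' segment, so the AUC equals the concordance (Mann-Whitney) statistic with
#' ties counted 1/2.
#'
#' @param scores Numeric classification scores (higher = more vMCI-like).
#' @param truth 0/1 labels; both classes must be present.
#' @return A list of class `roc_result`: `points` (data frame `fpr`, `tpr`,
#'   monotone nondecreasing in both coordinates) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  if (length(unique(truth)) < 2) stop("truth must contain both classes")
  stopifnot(all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # cumulative counts at each unique-score cut (predict 1 when score >= cut)
  cut_end <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, cumsum(t == 1)[cut_end] / n_pos)
  fpr <- c(0, cumsum(t == 0)[cut_end] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' McNemar's paired classifier comparison
#'
#' Compares two classifiers on the same subjects through their discordant
#' classifications: `b` subjects correct under A but wrong under B, `c` the
#' reverse. For `b + c >= 25` the continuity-corrected chi-square form
#' `(|b - c| - 1)^2 / (b + c)` on 1 df is used; for smaller discordant counts
#' the exact two-sided binomial(b + c, 1/2) test on `min(b, c)`. With no
#' discordant pairs the degenerate convention statistic 0, p = 1 (exact)
#' applies. A test on the paired 0.5-threshold classifications, not on AUCs.
#'
#' @param preds_A,preds_B 0/1 predictions of the two classifiers.
#' @param truth 0/1 true labels.
#' @param correct Apply the continuity correction in the chi-square form
#'   (default TRUE).
#' @return A list of class `mcnemar_result`: `b`, `c`, `statistic`, `p`,
#'   `method` (`"chi-square-corrected"`, `"chi-square"` or
#'   `"exact-binomial"`).
#' @export
mcnemar_compare <- function(preds_A, preds_B, truth, correct = TRUE) {
  if (length(preds_A) != length(truth) || length(preds_B) != length(truth))
    stop("length mismatch")
  okA <- preds_A == truth
  okB <- preds_B == truth
  b <- sum(okA & !okB)
  cc <- sum(!okA & okB)
  if (b + cc == 0) {
    return(structure(list(b = b, c = cc, statistic = 0, p = 1,
                          method = "exact-binomial"),
                     class = "mcnemar_result"))
  }
  if (b + cc >= 25) {
    num <- if (correct) (abs(b - cc) - 1)^2 else (b - cc)^2
    stat <- num / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- if (correct) "chi-square-corrected" else "chi-square"
  } else {
    stat <- min(b, cc)
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact-binomial"
  }
  structure(list(b = b, c = cc, statistic = stat, p = p, method = method),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, statistic = %.4g, p = %.4g\n",
              x$method, x$b, x$c, x$statistic, x$p))
  invisible(x)
}
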