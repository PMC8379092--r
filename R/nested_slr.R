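# Main modelling interface: nested_slr() runs nested lasso feature selection
# followed by leave-one-out sparse logistic regression on one modality subset
# of a cohort and returns a classed fit with the usual S3 methods.

#' Nested-selection sparse logistic classifier
#'
#' Fits the full discrimination procedure on a cohort: (1) 10x10 nested lasso
#' feature selection with (diagnosis, sex)-stratified folds, yielding ten
#' testing pools with pool-shared reduced feature sets; (2) leave-one-out
#' cross-validated L1-penalized logistic regression, each subject predicted by
#' a model trained without it on its pool's reduced features; (3) consensus
#' discriminative features as those with nonzero classifier weight in at
#' least `threshold` of the LOOCV folds; (4) confusion metrics and ROC/AUC of
#' the LOOCV predictions; (5) a final sparse logistic model refit on the
#' consensus features of the whole cohort, used by [predict.nested_slr()] for
#' new data (reported separately from the LOOCV summaries, which never see
#' this refit).
#'
#' One global seed fans out deterministically to the selection and
#' classification stages, and all randomness is keyed to sorted subject ids,
#' so results do not depend on input row order.
#'
#' @param cohort An `svd_cohort` (see [load_cohort()], [generate_cohort()]).
#' @param modality Feature subset: `"combined"`, `"diffusion"` or
#'   `"perfusion"`.
#' @param threshold Consensus frequency threshold (inclusive), default 0.75.
#' @param lasso A [lasso_config()] for the selection stage.
#' @param logit A [logit_config()] for the classification stage.
#' @param n_outer,n_inner Fold counts of the nested selection.
#' @param seed Integer global seed.
#' @return An object of class `nested_slr`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_paper_config(seed = 7))
#' fit <- nested_slr(cohort, "combined", seed = 7)
#' print(fit)
#' }
#' @export
nested_slr <- function(cohort, modality = c("combined", "diffusion", "perfusion"),
                       threshold = 0.75, lasso = lasso_config(),
                       logit = logit_config(), n_outer = 10, n_inner = 10,
                       seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(inherits(cohort, "svd_cohort"))
  sub <- subset_modality(cohort, modality)
  reduced <- nested_fs(sub, lasso, seed = derive_seed(seed, "selection"),
                       n_outer = n_outer, n_inner = n_inner)
  loocv <- loocv_run(sub, reduced, logit,
                     seed = derive_seed(seed, "classification"))
  consensus <- consensus_features(loocv, threshold)
  pr <- loocv$predictions
  metrics <- confusion_metrics(pr$pred, pr$y)
  roc <- roc_auc(pr$prob, pr$y)

  final_model <- NULL
  if (length(consensus$consensus)) {
    Xc <- sub$features[, consensus$consensus, drop = FALSE]
    lam <- cv_lambda_logit(Xc, pr$y, logit,
                           seed = derive_seed(seed, "final_model"))
    final_model <- fit_sparse_logistic(Xc, pr$y, lam, logit)
  }
  structure(list(call = match.call(), modality = modality,
                 n = nrow(pr), n_features = ncol(sub$features),
                 reduced = reduced, loocv = loocv, consensus = consensus,
                 metrics = metrics, roc = roc, final_model = final_model,
                 threshold = threshold, seed = as.integer(seed)),
            class = "nested_slr")
}

#' @export
print.nested_slr <- function(x, ...) {
  cat(sprintf("Nested-selection sparse logistic classifier (%s features)\n",
              x$modality))
  cat(sprintf("  %d subjects, %d features entering selection\n", x$n, x$n_features))
  cat(sprintf("  LOOCV: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
              x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity, x$roc$auc))
  cat(sprintf("  Consensus features (frequency >= %.2f): %d\n",
              x$threshold, length(x$consensus$consensus)))
  invisible(x)
}

#' @export
summary.nested_slr <- function(object, ...) {
  structure(list(fit = object,
                 pool_sizes = vapply(object$reduced$pools,
                                     function(p) length(p$features), integer(1)),
                 consensus_table = object$consensus$table),
            class = "summary.nested_slr")
}

#' @export
print.summary.nested_slr <- function(x, ...) {
  print(x$fit)
  cat("  Reduced-set sizes per testing pool:",
      paste(x$pool_sizes, collapse = "/"), "\n")
  top <- utils::head(x$consensus_table, 15)
  cat("  Top selection frequencies:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Coefficients of the final consensus-feature model
#'
#' Returns the weight vector of the sparse logistic model refit on the
#' consensus features (standardized scale, augmented convention: named feature
#' weights followed by `(Intercept)`).
#'
#' @param object A `nested_slr` fit.
#' @param ... Unused.
#' @export
coef.nested_slr <- function(object, ...) {
  if (is.null(object$final_model))
    stop("no final model: the consensus feature set is empty")
  m <- object$final_model
  stats::setNames(m$weights, c(m$features, "(Intercept)"))
}

#' Predict vMCI probabilities for new subjects
#'
#' Uses the final consensus-feature model. For `type = "loocv"` no new data
#' are needed: the leave-one-out predictions of the fit are returned.
#'
#' @param object A `nested_slr` fit.
#' @param newdata An `svd_cohort` or a numeric matrix containing the consensus
#'   feature columns.
#' @param type `"prob"` (default), `"class"` (0.5 threshold), or `"loocv"`.
#' @param ... Unused.
#' @export
predict.nested_slr <- function(object, newdata = NULL,
                               type = c("prob", "class", "loocv"), ...) {
  type <- match.arg(type)
  if (type == "loocv") return(object$loocv$predictions)
  if (is.null(object$final_model))
    stop("no final model: the consensus feature set is empty")
  if (is.null(newdata)) stop("newdata required for type = '", type, "'")
  X <- if (inherits(newdata, "svd_cohort")) newdata$features else as.matrix(newdata)
  feats <- object$final_model$features
  missing_f <- setdiff(feats, colnames(X))
  if (length(missing_f)) stop("newdata lacks consensus feature(s): ",
                              paste(missing_f, collapse = ", "))
  p <- predict_prob(object$final_model, X[, feats, drop = FALSE])
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
fitted.nested_slr <- function(object, ...) {
  stats::setNames(object$loocv$predictions$prob,
                  object$loocv$predictions$subject_id)
}

#' @export
residuals.nested_slr <- function(object, ...) {
  pr <- object$loocv$predictions
  stats::setNames(pr$y - pr$prob, pr$subject_id)
}

#' Plot the LOOCV ROC curve
#'
#' @param x A `nested_slr` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nested_slr <- function(x, ...) {
  pts <- x$roc$points
  graphics::plot(pts$fpr, pts$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("LOOCV ROC (%s), AUC = %.3f",
                                x$modality, x$roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
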