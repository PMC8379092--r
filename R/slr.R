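# Sparse logistic regression: L1-penalized logistic likelihood (penalty on
# feature weights, never on the intercept), solved by cyclic coordinate
# descent inside iteratively reweighted least squares. The classifier assigns
# P(vMCI | z) = 1 / (1 + exp(-w' zhat)) with zhat the standardized feature
# vector augmented by 1 and w the (k+1)-dimensional weight vector.

#' Sparse logistic regression configuration
#'
#' @param n_lambda,lambda_min_ratio Geometric penalty path for the internal
#'   cross-validated choice of the logistic penalty.
#' @param tol Coordinate-descent tolerance (variance-weighted squared change
#'   criterion, as in [lasso_config()]).
#' @param tol_irls Outer IRLS convergence tolerance: relative change of the
#'   penalized objective (mean negative log-likelihood plus penalty) between
#'   successive reweightings.
#' @param maxit Maximum coordinate-descent sweeps per inner solve.
#' @param maxit_irls Maximum IRLS iterations.
#' @param cv_folds Folds for the internal deviance-based penalty choice.
#' @param cv_rule `"1se"` (default) picks the largest penalty whose
#'   cross-validated deviance is within one standard error of the minimum --
#'   the standard choice when the model is wanted sparse; `"min"` picks the
#'   deviance-minimizing penalty.
#' @return A list of class `logit_config`.
#' @export
logit_config <- function(n_lambda = 30, lambda_min_ratio = 0.01,
                         tol = 1e-12, tol_irls = 1e-9,
                         maxit = 1e5, maxit_irls = 100, cv_folds = 10,
                         cv_rule = c("1se", "min")) {
  structure(list(n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 tol = tol, tol_irls = tol_irls,
                 maxit = as.integer(maxit),
                 maxit_irls = as.integer(maxit_irls),
                 cv_folds = as.integer(cv_folds),
                 cv_rule = match.arg(cv_rule)),
            class = "logit_config")
}

#' Fit an L1-penalized (sparse) logistic regression
#'
#' Minimizes the penalized negative log-likelihood
#' `(1/n) sum_i [log(1 + exp(eta_i)) - y_i eta_i] + lambda ||w_feat||_1`
#' where `eta = w' zhat` and the intercept is unpenalized. Predictors are
#' standardized internally using the training rows; the standardization
#' parameters are stored in the model and re-applied at prediction time.
#' Deterministic given its inputs.
#'
#' @param X Numeric training matrix over a reduced feature set.
#' @param y 0/1 labels (1 = vMCI); both classes must be present.
#' @param lambda Non-negative penalty on the feature weights.
#' @param config A [logit_config()].
#' @return An object of class `slr_model`: `features` (column names, size k),
#'   `weights` (length k+1; augmented convention, intercept last, standardized
#'   scale), `lambda`, `center`, `scale`.
#' @export
fit_sparse_logistic <- function(X, y, lambda, config = logit_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (ncol(X) == 0L) stop("reduced feature set is empty")
  if (lambda < 0) stop("lambda must be non-negative")
  std <- standardize_columns(X)
  Xs <- std$X
  p <- ncol(Xs)

  beta <- numeric(p)
  b0 <- stats::qlogis(mean(y))
  obj_prev <- Inf
  for (it in seq_len(config$maxit_irls)) {
    eta <- drop(Xs %*% beta) + b0
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    fit <- .cd_lasso_path(Xs, z, w, lambda, config$tol, config$maxit,
                          beta, b0, TRUE)
    if (!fit$converged[1])
      stop(sprintf("inner coordinate descent did not converge at lambda = %g", lambda))
    beta <- fit$beta[, 1]
    b0 <- fit$b0[1]
    eta <- drop(Xs %*% beta) + b0
    obj <- mean(log1p(exp(eta)) - y * eta) + lambda * sum(abs(beta))
    if (is.finite(obj_prev) && abs(obj_prev - obj) < config$tol_irls * (abs(obj) + 0.1)) {
      if (lambda == 0 && max(abs(eta)) > 25)
        stop("logistic fit diverged at lambda = 0 (perfect separation); use lambda > 0")
      nm <- colnames(X) %||% as.character(seq_len(p))
      return(structure(list(features = nm, weights = c(beta, b0), lambda = lambda,
                            center = std$center,
                            scale = ifelse(is.na(std$scale), 1, std$scale),
                            iters = it),
                       class = "slr_model"))
    }
    obj_prev <- obj
  }
  if (lambda == 0)
    stop("IRLS did not converge at lambda = 0 (possible perfect separation); use lambda > 0")
  stop(sprintf("IRLS did not converge within %d iterations at lambda = %g",
               config$maxit_irls, lambda))
}

#' Predicted vMCI probability
#'
#' Applies the model's stored training standardization to the feature vector,
#' augments it with 1, and returns `1 / (1 + exp(-w' zhat))`.
#'
#' @param model An `slr_model`.
#' @param features Numeric vector of length k, or a matrix with k columns
#'   (column names, if present, must match the model's features; storage order
#'   does not matter).
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "slr_model"))
  k <- length(model$features)
  if (is.null(dim(features))) {
    if (length(features) != k)
      stop(sprintf("feature vector length %d does not match model size %d",
                   length(features), k))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(features)
  if (ncol(features) != k)
    stop(sprintf("feature matrix has %d columns; model expects %d",
                 ncol(features), k))
  if (!is.null(colnames(features))) {
    if (!setequal(colnames(features), model$features))
      stop("feature names do not match the model")
    features <- features[, model$features, drop = FALSE]
  }
  zs <- sweep(sweep(features, 2L, model$center), 2L, model$scale, `/`)
  eta <- drop(zs %*% model$weights[seq_len(k)]) + model$weights[k + 1L]
  stats::plogis(eta)
}

#' @export
print.slr_model <- function(x, ...) {
  k <- length(x$features)
  cat(sprintf("Sparse logistic model: %d features (%d nonzero weights), lambda = %.5g\n",
              k, sum(x$weights[seq_len(k)] != 0), x$lambda))
  invisible(x)
}

# logistic path entry point on a standardized design
lambda_max_logit <- function(Xs, y) {
  max(abs(crossprod(Xs, y - mean(y)))) / nrow(Xs)
}

# IRLS path on a pre-standardized design, warm-started down the lambda
# sequence; returns standardized-scale weights per lambda. Internal.
logit_path_std <- function(Xs, y, lambdas, config) {
  p <- ncol(Xs)
  beta <- numeric(p)
  b0 <- stats::qlogis(mean(y))
  betas <- matrix(NA_real_, p, length(lambdas))
  b0s <- numeric(length(lambdas))
  for (l in seq_along(lambdas)) {
    obj_prev <- Inf
    for (it in seq_len(config$maxit_irls)) {
      eta <- drop(Xs %*% beta) + b0
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-5)
      z <- eta + (y - mu) / w
      fit <- .cd_lasso_path(Xs, z, w, lambdas[l], config$tol, config$maxit,
                            beta, b0, TRUE)
      beta <- fit$beta[, 1]
      b0 <- fit$b0[1]
      eta <- drop(Xs %*% beta) + b0
      obj <- mean(log1p(exp(eta)) - y * eta) + lambdas[l] * sum(abs(beta))
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) < config$tol_irls * (abs(obj) + 0.1)) break
      obj_prev <- obj
    }
    betas[, l] <- beta
    b0s[l] <- b0
  }
  list(beta = betas, b0 = b0s)
}

# k-fold CV choice of the logistic penalty by mean held-out deviance;
# ties broken toward the larger (sparser) lambda. Deterministic given seed.
cv_lambda_logit <- function(X, y, config = logit_config(), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- min(config$cv_folds, min(table(y)))
  if (k < 2) stop("too few subjects per class for penalty cross-validation")
  std <- standardize_columns(X)
  usable <- !is.na(std$scale)
  lmax <- lambda_max_logit(std$X[, usable, drop = FALSE], y)
  if (lmax <= 0) lmax <- .Machine$double.eps
  lambdas <- exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
                     length.out = config$n_lambda))
  folds <- with_seed(seed, make_strat_folds(as.character(y), k))
  dev <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- folds != f
    # standardize within the training portion only
    stdf <- standardize_columns(X[tr, , drop = FALSE])
    path <- logit_path_std(stdf$X, y[tr], lambdas, config)
    scl <- ifelse(is.na(stdf$scale), 1, stdf$scale)
    Xv <- sweep(sweep(X[!tr, , drop = FALSE], 2L, stdf$center), 2L, scl, `/`)
    eta <- sweep(Xv %*% path$beta, 2L, path$b0, `+`)
    pr <- stats::plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    dev[f, ] <- -2 * colMeans(y[!tr] * log(pr) + (1 - y[!tr]) * log(1 - pr))
  }
  cvm <- colMeans(dev)
  if (config$cv_rule == "1se") {
    cvse <- apply(dev, 2L, stats::sd) / sqrt(k)
    thr <- min(cvm) + cvse[which.min(cvm)]
    lambdas[which(cvm <= thr)[1]]
  } else {
    lambdas[which.min(cvm)]
  }
}

#' Leave-one-out cross-validated classification
#'
#' For each subject: locate the testing pool containing it, train a sparse
#' logistic classifier on all other subjects restricted to that pool's reduced
#' feature set, and record the predicted vMCI probability, the 0.5-threshold
#' label, and the trained model's nonzero-weight feature set. The logistic
#' penalty is chosen once per pool by internal cross-validation on the
#' subjects outside the pool. A pool with an empty reduced set has its
#' subjects predicted at the training base rate, with a warning.
#'
#' @param cohort An `svd_cohort`.
#' @param reduced A [nested_fs()] result whose pools cover the cohort.
#' @param config A [logit_config()].
#' @param seed Integer seed (per-pool penalty cross-validation).
#' @return An object of class `slr_loocv`: `predictions` data frame (one row
#'   per subject: `subject_id`, `y`, `prob`, `pred`, `pool`), `fold_features`
#'   (named list, per subject, of that fold's nonzero-weight features),
#'   `pool_lambda`, `reduced`, `seed`.
#' @export
loocv_run <- function(cohort, reduced, config = logit_config(), seed = 1L) {
  stopifnot(inherits(reduced, "reduced_feature_sets"))
  ph <- cohort$phenotype
  ids <- ph$subject_id
  covered <- unlist(lapply(reduced$pools, `[[`, "pool"))
  if (!setequal(covered, ids))
    stop("testing pools do not partition the cohort")
  y <- ph$diagnosis
  names(y) <- ids

  pool_lambda <- rep(NA_real_, length(reduced$pools))
  prob <- stats::setNames(rep(NA_real_, length(ids)), ids)
  fold_features <- stats::setNames(vector("list", length(ids)), ids)
  pool_ix <- stats::setNames(rep(NA_integer_, length(ids)), ids)

  for (pi in seq_along(reduced$pools)) {
    pool <- reduced$pools[[pi]]
    feats <- pool$features
    pool_ix[pool$pool] <- pi
    outside <- setdiff(ids, pool$pool)
    if (length(feats) == 0L) {
      warning("pool ", pi, " has an empty reduced feature set; ",
              "predicting its subjects at the training base rate")
      for (s in pool$pool) {
        prob[s] <- mean(y[setdiff(ids, s)])
        fold_features[[s]] <- character(0)
      }
      next
    }
    pool_lambda[pi] <- cv_lambda_logit(
      cohort$features[outside, feats, drop = FALSE], y[outside], config,
      seed = derive_seed(seed, paste0("pool_lambda_", pi)))
    for (s in pool$pool) {
      tr <- setdiff(ids, s)
      m <- fit_sparse_logistic(cohort$features[tr, feats, drop = FALSE],
                               y[tr], pool_lambda[pi], config)
      prob[s] <- predict_prob(m, cohort$features[s, feats])
      fold_features[[s]] <- m$features[m$weights[seq_along(m$features)] != 0]
    }
  }
  structure(list(
    predictions = data.frame(subject_id = ids, y = y, prob = unname(prob[ids]),
                             pred = as.integer(prob[ids] >= 0.5),
                             pool = unname(pool_ix[ids]),
                             stringsAsFactors = FALSE, row.names = NULL),
    fold_features = fold_features, pool_lambda = pool_lambda,
    reduced = reduced, seed = as.integer(seed)
  ), class = "slr_loocv")
}

#' Consensus discriminative features
#'
#' Computes, for every feature, the fraction of leave-one-out folds in which
#' it was selected, and applies an inclusive frequency threshold (default
#' 0.75): features selected in at least 75% of folds are the consensus
#' discriminative features.
#'
#' Two frequency semantics are available. The default, `"weights"`, counts
#' the folds in which the feature carried a nonzero weight in that fold's
#' sparse classifier. `"reduced"` instead counts membership in the fold's
#' pool-shared reduced feature set (which can only take values that are sums
#' of pool-size fractions).
#'
#' @param result An [loocv_run()] result.
#' @param threshold Frequency threshold in (0, 1]; comparison is inclusive.
#' @param semantics `"weights"` (default) or `"reduced"`.
#' @return An object of class `consensus_set`: `table` (data frame `feature`,
#'   `frequency`, sorted by decreasing frequency), `consensus` (character
#'   vector), `threshold`, `semantics`.
#' @export
consensus_features <- function(result, threshold = 0.75,
                               semantics = c("weights", "reduced")) {
  stopifnot(inherits(result, "slr_loocv"))
  semantics <- match.arg(semantics)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  n <- nrow(result$predictions)
  all_feats <- sort(unique(unlist(lapply(result$reduced$pools, `[[`, "features"))))
  if (semantics == "weights") {
    counts <- table(unlist(result$fold_features))
    freq <- stats::setNames(rep(0, length(all_feats)), all_feats)
    freq[names(counts)] <- as.numeric(counts) / n
  } else {
    freq <- stats::setNames(rep(0, length(all_feats)), all_feats)
    for (pool in result$reduced$pools)
      freq[pool$features] <- freq[pool$features] + length(pool$pool) / n
  }
  tab <- data.frame(feature = names(freq), frequency = unname(freq),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  consensus <- tab$feature[tab$frequency >= threshold]
  if (length(consensus) == 0L)
    warning("no feature reaches the consensus frequency threshold of ", threshold)
  structure(list(table = tab, consensus = consensus, threshold = threshold,
                 semantics = semantics),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("Consensus features (frequency >= %.2f, %s semantics): %d of %d\n",
              x$threshold, x$semantics, length(x$consensus), nrow(x$table)))
  if (length(x$consensus))
    print(utils::head(x$table[x$table$frequency >= x$threshold, ], 20),
          row.names = FALSE)
  invisible(x)
}
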