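# Linear (least-squares) lasso by cyclic coordinate descent, used as the
# feature-selection engine: the 0/1 diagnosis label is regressed on the
# feature columns under an L1 penalty, with internal standardization inside
# each fit (using only that fit's rows, so cross-validation never leaks) and
# back-transformation of coefficients to the input scale.

#' Lasso solver configuration
#'
#' @param n_lambda Number of points on the geometric regularization path.
#' @param lambda_min_ratio Smallest path lambda as a fraction of `lambda_max`.
#' @param tol Convergence tolerance on the maximum variance-weighted squared
#'   coefficient change per sweep (the reference coordinate-descent
#'   convention; on unit-variance predictors 1e-7 corresponds to coefficient
#'   changes of about 3e-4). Oracle-agreement checks pass a tighter value.
#' @param maxit Maximum coordinate-descent sweeps per lambda.
#' @param cv_folds Folds for the internal cross-validated lambda choice.
#' @param cv_rule `"min"` picks the lambda minimizing CV mean squared error
#'   (ties broken toward the larger, sparser lambda); `"1se"` picks the
#'   largest lambda whose CV error is within one standard error of the
#'   minimum.
#' @return A list of class `lasso_config`.
#' @export
lasso_config <- function(n_lambda = 100, lambda_min_ratio = 1e-4,
                         tol = 1e-7, maxit = 1e5, cv_folds = 10,
                         cv_rule = c("min", "1se")) {
  stopifnot(lambda_min_ratio > 0, lambda_min_ratio < 1, tol > 0,
            n_lambda >= 1, cv_folds >= 2)
  structure(list(n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 tol = tol, maxit = as.integer(maxit),
                 cv_folds = as.integer(cv_folds),
                 cv_rule = match.arg(cv_rule)),
            class = "lasso_config")
}

# Column standardization with 1/n variance (population) convention; returns
# scaled matrix plus centers/scales. Constant columns get scale NA and a
# zeroed column so their coefficient stays exactly zero.
standardize_columns <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colSums(Xc^2) / n)
  const <- scl <= 0
  scl_safe <- ifelse(const, 1, scl)
  Xs <- sweep(Xc, 2L, scl_safe, `/`)
  if (any(const)) Xs[, const] <- 0
  list(X = Xs, center = ctr, scale = ifelse(const, NA_real_, scl))
}

#' Entry point of the lasso path
#'
#' For standardized predictors and a centered response, the smallest penalty
#' at which the lasso solution is identically zero is
#' `max_j |<x_j, y>| / n`.
#'
#' @param X Numeric matrix with columns standardized (zero mean, unit 1/n
#'   variance) on the given rows. A zero-variance column is an error; drop it
#'   upstream.
#' @param y Centered numeric response.
#' @return The scalar path entry point.
#' @export
lambda_max <- function(X, y) {
  X <- as.matrix(X)
  v <- colSums(sweep(X, 2L, colMeans(X))^2) / nrow(X)
  if (any(v <= .Machine$double.eps * 100))
    stop("zero-variance predictor column(s); drop them before calling lambda_max")
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

#' Fit the lasso at a fixed penalty
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` by cyclic coordinate
#' descent with internal standardization; coefficients are reported on the
#' input scale. Coefficients with absolute value below 1e-12 after
#' back-transformation are treated as exact zeros for support purposes.
#'
#' @param X Numeric predictor matrix (any scale; standardized internally
#'   using these rows only).
#' @param y Numeric response (the 0/1 diagnosis label, treated as real).
#' @param lambda Non-negative penalty (standardized scale).
#' @param config A [lasso_config()].
#' @return A list of class `lasso_fit` with elements `lambda`,
#'   `coefficients` (input scale), `intercept`, `support` (character vector of
#'   selected column names, or indices when unnamed) and `iters`.
#' @export
lasso_fit <- function(X, y, lambda, config = lasso_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows")
  if (lambda < 0) stop("lambda must be non-negative")
  std <- standardize_columns(X)
  if (all(is.na(std$scale))) stop("all predictor columns are constant")
  ybar <- mean(y)
  fit <- .cd_lasso_path(std$X, y - ybar, rep(1, n), lambda,
                        config$tol, config$maxit,
                        numeric(ncol(X)), 0, FALSE)
  if (!fit$converged[1])
    stop(sprintf("lasso did not converge at lambda = %g within %d sweeps",
                 lambda, config$maxit))
  beta_std <- fit$beta[, 1]
  beta <- ifelse(is.na(std$scale), 0, beta_std / ifelse(is.na(std$scale), 1, std$scale))
  beta[abs(beta) < 1e-12] <- 0
  intercept <- ybar - sum(beta * std$center)
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  names(beta) <- nm
  structure(list(lambda = lambda, coefficients = beta, intercept = intercept,
                 support = nm[beta != 0], iters = fit$iters[1]),
            class = "lasso_fit")
}

# Full path fit on given rows; returns back-transformed coefficient matrix.
# Used internally by cross-validation (warm starts down the path, with
# saturation-based early stopping: once the training R^2 exceeds 0.999, gains
# less than 1e-5 per step, or the active set exceeds the row count, remaining
# path points reuse the last solution -- the saturated tail is degenerate in
# the p > n regime and never wins cross-validation).
lasso_path_fit <- function(X, y, lambdas, config) {
  std <- standardize_columns(X)
  ybar <- mean(y)
  fit <- .cd_lasso_path(std$X, y - ybar, rep(1, nrow(X)), lambdas,
                        config$tol, config$maxit,
                        numeric(ncol(X)), 0, FALSE,
                        TRUE, 1e-5, 0.999, nrow(X))
  if (!all(fit$converged))
    stop(sprintf("lasso path did not converge at lambda = %g within %d sweeps",
                 lambdas[which(!fit$converged)[1]], config$maxit))
  scl <- ifelse(is.na(std$scale), 1, std$scale)
  beta <- fit$beta / scl
  beta[is.na(std$scale), ] <- 0
  intercepts <- ybar - drop(crossprod(beta, std$center))
  list(beta = beta, intercept = intercepts, lambdas = lambdas)
}

lambda_grid <- function(lmax, config) {
  if (config$n_lambda == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

#' Choose the lasso penalty by internal cross-validation
#'
#' Evaluates a geometric path of `n_lambda` values from `lambda_max` down to
#' `lambda_max * lambda_min_ratio` by k-fold cross-validated mean squared
#' prediction error (folds stratified by the 0/1 response) and returns the
#' penalty minimizing it, ties broken toward the larger (sparser) value.
#' Deterministic given `seed`.
#'
#' @inheritParams lasso_fit
#' @param seed Integer seed controlling the fold assignment.
#' @return A list with `lambda_star`, the CV `path` summary (data frame with
#'   `lambda`, `cvm`, `cvse`, `nonzero`), and the `rule` used.
#' @export
cv_select_lambda <- function(X, y, config = lasso_config(), seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  k <- config$cv_folds
  if (n < 2 * k) stop("need at least 2 observations per CV fold")
  if (stats::var(y) == 0) stop("constant response; cannot cross-validate")

  std_all <- standardize_columns(X)
  usable <- !is.na(std_all$scale)
  if (!any(usable)) stop("all predictor columns are constant")
  lmax <- max(abs(crossprod(std_all$X[, usable, drop = FALSE], y - mean(y)))) / n
  if (lmax <= 0) lmax <- .Machine$double.eps
  lambdas <- lambda_grid(lmax, config)

  # stratify on the response values themselves (binary labels in practice)
  folds <- with_seed(seed, make_strat_folds(as.character(y), k))

  errs <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- folds != f
    pf <- lasso_path_fit(X[tr, , drop = FALSE], y[tr], lambdas, config)
    pred <- X[!tr, , drop = FALSE] %*% pf$beta
    pred <- sweep(pred, 2L, pf$intercept, `+`)
    errs[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(errs)
  cvse <- apply(errs, 2L, stats::sd) / sqrt(k)
  if (config$cv_rule == "min") {
    best <- which.min(cvm)            # first index = largest lambda among ties
  } else {
    thr <- min(cvm) + cvse[which.min(cvm)]
    best <- which(cvm <= thr)[1]
  }
  full <- lasso_path_fit(X, y, lambdas, config)
  nonzero <- colSums(abs(full$beta) > 1e-12)
  list(lambda_star = lambdas[best],
       path = data.frame(lambda = lambdas, cvm = cvm, cvse = cvse,
                         nonzero = nonzero),
       rule = config$cv_rule)
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("Lasso fit: lambda = %.6g, %d of %d coefficients nonzero\n",
              x$lambda, length(x$support), length(x$coefficients)))
  invisible(x)
}
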