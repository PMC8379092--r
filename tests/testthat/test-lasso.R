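# The linear lasso solver against closed-form and reference oracles.

tight <- lasso_config(tol = 1e-14)

test_that("lambda_max matches its definition and zeroes the fit", {
  n <- 40
  X <- orthonormal_design(n, 3)
  # y orthogonal to all columns
  y0 <- residuals(lm.fit(cbind(1, X), rnorm(n)))
  expect_equal(lambda_max(X, y0), 0, tolerance = 1e-12)

  # single column with <x, y>/n = 0.4
  x <- orthonormal_design(n, 1)
  y <- 0.4 * x[, 1] + residuals(lm.fit(cbind(1, x), rnorm(n)))
  y <- y - mean(y)
  expect_equal(lambda_max(x, y), abs(sum(x * y)) / n, tolerance = 1e-12)

  expect_error(lambda_max(cbind(X, 0), y0), "zero-variance")

  # fit just above lambda_max has empty support; intercept is mean(y)
  withr::with_seed(7, {
    X2 <- matrix(rnorm(20 * 5), 20, 5)
    y2 <- rnorm(20)
  })
  lm_ <- lambda_max(nestedSLR:::standardize_columns(X2)$X, y2 - mean(y2))
  f <- lasso_fit(X2, y2, 1.01 * lm_, tight)
  expect_length(f$support, 0)
  expect_equal(f$intercept, mean(y2), tolerance = 1e-10)
})

test_that("orthonormal designs give exact soft-thresholding solutions", {
  n <- 60; p <- 8
  X <- orthonormal_design(n, p)
  withr::with_seed(3, b <- rnorm(p, 0, 1))
  y <- drop(X %*% b) + withr::with_seed(4, rnorm(n, 0, 0.3))
  z <- drop(crossprod(X, y)) / n
  for (lam in c(0.05, 0.2, 0.6)) {
    f <- lasso_fit(X, y, lam, tight)
    expected <- sign(z) * pmax(abs(z) - lam, 0)
    expect_equal(unname(f$coefficients), expected, tolerance = 1e-8)
  }
})

test_that("lambda = 0 on a full-rank design reproduces least squares", {
  withr::with_seed(11, {
    X <- matrix(rnorm(80 * 6), 80, 6)
    y <- drop(X %*% runif(6, -1, 1)) + rnorm(80)
  })
  f <- lasso_fit(X, y, 0, tight)
  ols <- coef(lm.fit(cbind(1, X), y))
  expect_equal(unname(f$intercept), unname(ols[1]), tolerance = 1e-6)
  expect_equal(unname(f$coefficients), unname(ols[-1]), tolerance = 1e-6)
})

test_that("KKT conditions hold at convergence", {
  withr::with_seed(21, {
    X <- matrix(rnorm(70 * 12), 70, 12)
    y <- drop(X %*% c(1, -1, rep(0, 10))) + rnorm(70, 0, 0.5)
  })
  lam <- 0.1
  f <- lasso_fit(X, y, lam, tight)
  std <- nestedSLR:::standardize_columns(X)
  beta_std <- f$coefficients * std$scale
  r <- y - mean(y) - drop(std$X %*% beta_std)
  g <- drop(crossprod(std$X, r)) / nrow(X)
  tol <- 1e-6
  expect_true(all(abs(g[beta_std == 0]) <= lam + tol))
  expect_true(all(abs(abs(g[beta_std != 0]) - lam) <= tol))
  expect_true(all(sign(g[beta_std != 0]) == sign(beta_std[beta_std != 0])))
})

test_that("support is monotone nonincreasing in lambda on orthonormal designs", {
  X <- orthonormal_design(50, 6)
  withr::with_seed(5, y <- drop(X %*% rnorm(6)) + rnorm(50, 0, 0.2))
  lams <- seq(0.01, 1, length.out = 25)
  sizes <- vapply(lams, function(l) length(lasso_fit(X, y, l, tight)$support),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("solver agrees with glmnet on random instances", {
  skip_if_not_installed("glmnet")
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      n <- 50 + s; p <- 10
      X <- matrix(rnorm(n * p), n, p)
      beta <- rnorm(p) * rbinom(p, 1, 0.4)
      y <- drop(X %*% beta) + rnorm(n)
      lam <- runif(1, 0.02, 0.5)
    })
    ours <- lasso_fit(X, y, lam, tight)
    ref <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = c(lam * 2, lam), thresh = 1e-14,
                          standardize = TRUE)
    bref <- as.numeric(ref$beta[, 2])
    expect_equal(unname(which(ours$coefficients != 0)), which(bref != 0))
    expect_lt(max(abs(ours$coefficients - bref)), 1e-4)
  }
})

test_that("cross-validated lambda choice recovers a planted support", {
  hits <- 0L
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      X <- matrix(rnorm(80 * 50), 80, 50)
      y <- drop(X %*% c(2, -2, rep(0, 48))) + rnorm(80, 0, 0.5)
    })
    cv <- cv_select_lambda(X, y, seed = s)
    sup <- lasso_fit(X, y, cv$lambda_star)$support
    if (all(c("1", "2") %in% sup)) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("pure-noise responses give small cross-validated supports", {
  sizes <- integer(100)
  for (s in 1:100) {
    withr::with_seed(2000 + s, {
      X <- matrix(rnorm(40 * 20), 40, 20)
      y <- rnorm(40)
    })
    cv <- cv_select_lambda(X, y, seed = s)
    sizes[s] <- length(lasso_fit(X, y, cv$lambda_star)$support)
  }
  expect_lte(median(sizes), 3)
})

test_that("cv_select_lambda handles degenerate configurations", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- drop(X %*% c(1, rep(0, 4))) + rnorm(60, 0, 0.2)
  })
  one <- cv_select_lambda(X, y, lasso_config(n_lambda = 1), seed = 1)
  expect_equal(nrow(one$path), 1)
  expect_equal(one$lambda_star, one$path$lambda[1])
  expect_error(cv_select_lambda(X, rep(1, 60), seed = 1), "constant")
  expect_error(cv_select_lambda(X[1:10, ], y[1:10], seed = 1), "per CV fold")
  # ties break toward the sparser (larger) lambda by construction
  expect_identical(cv_select_lambda(X, y, seed = 3),
                   cv_select_lambda(X, y, seed = 3))
})
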