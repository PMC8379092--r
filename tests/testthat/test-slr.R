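# Sparse logistic regression, LOOCV orchestration, consensus rule.

make_model <- function(weights, k = length(weights) - 1) {
  structure(list(features = paste0("f", seq_len(k)), weights = weights,
                 lambda = 0.1, center = rep(0, k), scale = rep(1, k)),
            class = "slr_model")
}

test_that("predicted probability follows the logistic closed forms", {
  m <- make_model(c(1, -1, 0))          # w'z = z1 - z2
  expect_equal(predict_prob(m, c(0.5, 0.5)), 0.5)
  expect_equal(predict_prob(m, c(log(3), 0)), 0.75, tolerance = 1e-12)

  m_neg <- make_model(-c(1, -1, 0))
  z <- c(0.3, -1.2)
  expect_equal(predict_prob(m_neg, z), 1 - predict_prob(m, z), tolerance = 1e-12)

  expect_error(predict_prob(m, c(1, 2, 3)), "length")
  # storage order of named features must not matter
  X <- matrix(c(1, 2), 1, dimnames = list(NULL, c("f2", "f1")))
  expect_equal(predict_prob(m, X),
               predict_prob(m, X[, c("f1", "f2"), drop = FALSE]))
})

test_that("heavy penalty collapses to the base-rate intercept", {
  withr::with_seed(2, X <- matrix(rnorm(113 * 4), 113, 4))
  y <- rep(c(1, 0), c(74, 39))
  m <- fit_sparse_logistic(X, y, 5)
  expect_equal(unname(m$weights[1:4]), rep(0, 4))
  expect_equal(unname(m$weights[5]), log(74 / 39), tolerance = 1e-6)
})

test_that("unpenalized limit matches the IRLS logistic oracle", {
  withr::with_seed(13, {
    X <- matrix(rnorm(90 * 3), 90, 3)
    eta <- drop(X %*% c(0.8, -0.5, 0)) - 0.2
    y <- rbinom(90, 1, plogis(eta))
  })
  cfg <- logit_config(tol = 1e-16, tol_irls = 1e-13, maxit_irls = 200)
  m <- fit_sparse_logistic(X, y, 0, cfg)
  # compare on the standardized scale used by the model
  std <- nestedSLR:::standardize_columns(X)
  g2 <- glm.fit(cbind(std$X, 1), y, family = binomial())
  expect_equal(unname(m$weights), unname(coef(g2)), tolerance = 1e-5)
})

test_that("separable data keep the separating sign and error at lambda 0", {
  x <- matrix(c(-3, -2, -1.5, 1.5, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_sparse_logistic(x, y, 0.05)
  expect_gt(m$weights[1], 0)
  expect_error(fit_sparse_logistic(x, y, 0), "lambda > 0|separation")
})

test_that("swapping class labels negates the decision function", {
  withr::with_seed(31, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- rbinom(60, 1, plogis(X[, 1]))
  })
  cfg <- logit_config(tol = 1e-16, tol_irls = 1e-12)
  m1 <- fit_sparse_logistic(X, y, 0.05, cfg)
  m2 <- fit_sparse_logistic(X, 1 - y, 0.05, cfg)
  expect_equal(m1$weights, -m2$weights, tolerance = 1e-6)
  p1 <- predict_prob(m1, X)
  p2 <- predict_prob(m2, X)
  expect_equal(p1, 1 - p2, tolerance = 1e-6)
})

test_that("LOOCV never trains on the held-out subject and covers everyone", {
  co <- tiny_cohort(n_case = 18, n_control = 12, d = 1.5)
  red <- nested_fs(co, lasso_config(cv_folds = 5), seed = 5,
                   n_outer = 5, n_inner = 5)
  res <- loocv_run(co, red, seed = 5)
  pr <- res$predictions
  expect_equal(nrow(pr), nrow(co$phenotype))
  expect_setequal(pr$subject_id, co$phenotype$subject_id)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_equal(pr$pred, as.integer(pr$prob >= 0.5))
  # each subject's pool excludes it from the selection training set
  for (i in seq_len(nrow(pr))) {
    pool <- red$pools[[pr$pool[i]]]
    expect_true(pr$subject_id[i] %in% pool$pool)
    expect_false(pr$subject_id[i] %in% pool$train)
  }
})

test_that("an empty reduced set falls back to base-rate predictions", {
  co <- tiny_cohort(n_case = 12, n_control = 10)
  red <- nested_fs(co, lasso_config(cv_folds = 4), seed = 2,
                   n_outer = 4, n_inner = 4)
  red$pools[[1]]$features <- character(0)
  expect_warning(res <- loocv_run(co, red, seed = 2), "base rate")
  affected <- red$pools[[1]]$pool
  probs <- res$predictions$prob[res$predictions$subject_id %in% affected]
  expect_true(all(abs(probs - mean(co$phenotype$diagnosis)) < 0.05))
})

test_that("consensus frequencies and threshold semantics are exact", {
  # construct a LOOCV result by hand: 20 subjects, 2 pools
  ids <- sprintf("S%02d", 1:20)
  folds <- setNames(vector("list", 20), ids)
  for (i in 1:20) {
    folds[[i]] <- c("always", if (i <= 15) "borderline75",
                    if (i <= 14) "under75")
  }
  res <- structure(list(
    predictions = data.frame(subject_id = ids, y = rep(0:1, 10),
                             prob = 0.5, pred = 1, pool = rep(1:2, each = 10)),
    fold_features = folds,
    reduced = structure(list(pools = list(
      list(pool = ids[1:10], features = c("always", "borderline75", "under75")),
      list(pool = ids[11:20], features = c("always", "borderline75", "under75"))
    )), class = "reduced_feature_sets"),
    seed = 1L), class = "slr_loocv")

  cs <- consensus_features(res, threshold = 0.75)
  tab <- setNames(cs$table$frequency, cs$table$feature)
  expect_equal(unname(tab["always"]), 1.000)
  expect_equal(unname(tab["borderline75"]), 0.75)
  expect_equal(unname(tab["under75"]), 0.70)
  expect_setequal(cs$consensus, c("always", "borderline75"))  # inclusive bound

  # 0.74 at threshold 0.75 is excluded
  folds2 <- lapply(seq_along(ids), function(i) if (i <= 14) "f" else character(0))
  names(folds2) <- ids
  res$fold_features <- folds2
  res$reduced$pools[[1]]$features <- "f"
  res$reduced$pools[[2]]$features <- "f"
  cs2 <- suppressWarnings(consensus_features(res, threshold = 0.75))
  expect_equal(cs2$table$frequency, 0.7)
  expect_length(cs2$consensus, 0)
  expect_warning(consensus_features(res, 0.75), "no feature")

  # reduced-set membership semantics counts pool fractions
  res$reduced$pools[[1]]$features <- c("f", "g")
  cs3 <- suppressWarnings(consensus_features(res, 0.75, semantics = "reduced"))
  tab3 <- setNames(cs3$table$frequency, cs3$table$feature)
  expect_equal(unname(tab3["g"]), 0.5)
  expect_equal(unname(tab3["f"]), 1.0)
  expect_error(consensus_features(res, 0), "threshold")
})
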