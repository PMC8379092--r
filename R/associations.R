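# Covariate-adjusted partial correlations between discriminative features and
# cognitive scores, Benjamini-Hochberg FDR correction, and the group
# comparison tests (normality-gated t / rank-sum, chi-square on sex).

#' Partial Pearson correlation
#'
#' Residualizes `x` and `y` on the covariates plus an intercept by least
#' squares and returns the Pearson correlation of the residuals, with a
#' two-sided p-value from `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2 - #covariates`. With no covariates this reduces exactly to the
#' ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix (or NULL for none); must be full rank.
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= q + 2) stop("need n > #covariates + 2")
  if (q > 0) {
    Z <- cbind(1, as.matrix(covariates))
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z)) stop("rank-deficient covariate matrix")
    rx <- stats::residuals(stats::lm.fit(Z, x))
    ry <- stats::residuals(stats::lm.fit(Z, y))
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  if (sum(rx^2) <= 0 || sum(ry^2) <= 0)
    stop("zero residual variance; correlation undefined")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - q
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = df, n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' input order. Wraps `stats::p.adjust(method = "BH")` after validating the
#' input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Normality-gated two-group comparison
#'
#' Checks each group for normality with a Lilliefors-corrected
#' Kolmogorov-Smirnov test (parameters estimated from the data) at alpha =
#' 0.05. If both groups pass, a two-sample t-test is run (Welch by default);
#' otherwise the Wilcoxon rank-sum test with normal approximation and tie
#' correction. Groups smaller than 4 cannot be gated (the Lilliefors test
#' needs n >= 4) and fall through to the distribution-free rank-sum branch.
#'
#' @param values Numeric vector.
#' @param labels 0/1 group labels, both groups of size >= 3.
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @return A list with `test` (`"t"` or `"wilcoxon"`), `statistic`, `p`.
#' @export
group_compare <- function(values, labels, var_equal = FALSE) {
  stopifnot(length(values) == length(labels), all(labels %in% c(0, 1)))
  g0 <- values[labels == 0]
  g1 <- values[labels == 1]
  if (length(g0) < 3 || length(g1) < 3) stop("both groups must have size >= 3")
  if (stats::sd(g0) == 0 || stats::sd(g1) == 0)
    stop("degenerate (constant) group; comparison undefined")
  normal <- length(g0) >= 4 && length(g1) >= 4 &&
    nortest::lillie.test(g0)$p.value >= 0.05 &&
    nortest::lillie.test(g1)$p.value >= 0.05
  if (normal) {
    tt <- stats::t.test(g1, g0, var.equal = var_equal)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g1, g0, exact = FALSE,
                                              correct = TRUE))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without Yates continuity correction, 1 df.
#'
#' @param counts 2x2 matrix of non-negative counts; no zero marginals.
#' @return A list with `statistic`, `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(counts < 0) || sum(counts) == 0) stop("invalid counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in contingency table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Feature-cognition association table
#'
#' For every (consensus feature, cognitive test) pair within the requested
#' diagnostic group, computes the partial Pearson correlation controlling for
#' sex, age and education, then applies Benjamini-Hochberg FDR correction
#' within each cognitive test (across features, separately per group — the
#' default family; `fdr_family = "table"` adjusts across the whole grid).
#' Records are flagged significant at `p_fdr < 0.05`.
#'
#' @param cohort An `svd_cohort` with cognitive scores.
#' @param consensus A [consensus_features()] result, or a character vector of
#'   feature names.
#' @param tests Cognitive test names (default the four attention-executive
#'   tests).
#' @param group `"vMCI"` or `"control"`.
#' @param fdr_family `"per_test"` (default) or `"table"`.
#' @return A data frame of class `association_table`: `feature`, `test`,
#'   `group`, `r`, `p_raw`, `p_fdr`, `n`, `significant`.
#' @export
association_table <- function(cohort, consensus,
                              tests = c("TMT_A", "TMT_B", "Stroop_CT", "VFT"),
                              group = c("vMCI", "control"),
                              fdr_family = c("per_test", "table")) {
  group <- match.arg(group)
  fdr_family <- match.arg(fdr_family)
  feats <- if (inherits(consensus, "consensus_set")) consensus$consensus else as.character(consensus)
  if (length(feats) == 0L) stop("consensus feature set is empty")
  missing_f <- setdiff(feats, colnames(cohort$features))
  if (length(missing_f)) stop("feature(s) not in cohort: ",
                              paste(missing_f, collapse = ", "))
  ph <- cohort$phenotype
  missing_t <- setdiff(tests, names(ph))
  if (length(missing_t)) stop("cognitive test(s) not in phenotype: ",
                              paste(missing_t, collapse = ", "))
  keep <- ph$diagnosis == (if (group == "vMCI") 1 else 0)
  if (sum(keep) < 6) stop("too few subjects in group '", group, "'")
  covars <- cbind(sex = ph$sex[keep], age = ph$age[keep],
                  education = ph$education[keep])
  grid <- expand.grid(feature = feats, test = tests,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    partial_correlation(cohort$features[keep, grid$feature[i]],
                        ph[[grid$test[i]]][keep], covars)
  })
  grid$group <- group
  grid$r <- vapply(res, `[[`, 0, "r")
  grid$p_raw <- vapply(res, `[[`, 0, "p")
  grid$n <- vapply(res, function(z) as.integer(z$n), integer(1))
  if (fdr_family == "per_test") {
    grid$p_fdr <- NA_real_
    for (tst in unique(grid$test)) {
      sel <- grid$test == tst
      grid$p_fdr[sel] <- bh_fdr(grid$p_raw[sel])
    }
  } else {
    grid$p_fdr <- bh_fdr(grid$p_raw)
  }
  grid$significant <- grid$p_fdr < 0.05
  class(grid) <- c("association_table", "data.frame")
  grid
}

#' @export
print.association_table <- function(x, digits = 3, ...) {
  cat(sprintf("Feature-cognition associations (%s group, n = %d): %d records, %d significant at FDR < 0.05\n",
              x$group[1], x$n[1], nrow(x), sum(x$significant)))
  df <- as.data.frame(x)
  df$r <- round(df$r, digits)
  df$p_raw <- signif(df$p_raw, digits)
  df$p_fdr <- signif(df$p_fdr, digits)
  print(df[df$significant, c("feature", "test", "r", "p_raw", "p_fdr")],
        row.names = FALSE)
  invisible(x)
}
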