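# Partial correlations, FDR, group tests, chi-square, association table.

test_that("partial correlation matches residualization and recursion oracles", {
  # no covariates: reduces exactly to Pearson
  withr::with_seed(1, { x <- rnorm(30); y <- 0.5 * x + rnorm(30) })
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)

  # y == x gives r = 1
  expect_equal(partial_correlation(x, x, cbind(rnorm(30)))$r, 1, tolerance = 1e-12)

  # 6-point constructed data with one covariate: recursive closed form
  x6 <- c(1.2, -0.4, 2.1, 0.3, -1.5, 0.9)
  y6 <- c(0.7, -1.1, 1.9, 0.2, -0.8, 1.4)
  z6 <- c(0.1, -0.6, 1.3, -0.2, -1.0, 0.5)
  rxy <- cor(x6, y6); rxz <- cor(x6, z6); ryz <- cor(y6, z6)
  recursive <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_correlation(x6, y6, cbind(z6))$r, recursive,
               tolerance = 1e-10)

  # brute-force residualization oracle on random instances
  for (s in 1:10) {
    withr::with_seed(400 + s, {
      n <- 40
      Z <- matrix(rnorm(n * 3), n, 3)
      xx <- rnorm(n) + Z %*% c(1, 0, -1)
      yy <- rnorm(n) + Z %*% c(0.5, 1, 0)
    })
    rx <- residuals(lm(xx ~ Z)); ry <- residuals(lm(yy ~ Z))
    pc <- partial_correlation(drop(xx), drop(yy), Z)
    expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
    expect_equal(pc$df, n - 2 - 3)
    tt <- pc$r * sqrt(pc$df / (1 - pc$r^2))
    expect_equal(pc$p, 2 * pt(-abs(tt), pc$df), tolerance = 1e-12)
  }

  expect_error(partial_correlation(x6, y6, cbind(z6, z6)), "rank")
  expect_error(partial_correlation(rep(1, 6), y6), "residual variance")
  expect_error(partial_correlation(x6[1:4], y6[1:4], cbind(z6, y6, x6)[1:4, ]),
               "covariates")
})

test_that("Benjamini-Hochberg adjustment follows the step-up arithmetic", {
  expect_equal(bh_fdr(0.03), 0.03)  # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  for (s in 1:10) {
    p <- withr::with_seed(500 + s, runif(sample(2:40, 1))^2)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-14)
    expect_true(all(bh_fdr(p) >= p))
    expect_equal(bh_fdr(bh_fdr(p)) >= bh_fdr(p), rep(TRUE, length(p)))
  }
  # order-preserving on sorted inputs
  ps <- sort(withr::with_seed(9, runif(15)))
  expect_true(all(diff(bh_fdr(ps)) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("normality gate routes to the right two-sample test", {
  # published cohort MoCA summary: strongly separated normal groups -> t branch
  withr::with_seed(64, {
    g1 <- rnorm(74, 21.72, 3.43)
    g0 <- rnorm(39, 26.33, 1.23)
  })
  gc <- group_compare(c(g1, g0), rep(c(1, 0), c(74, 39)))
  expect_equal(gc$test, "t")
  expect_lt(gc$p, 0.001)
  expect_gt(abs(gc$statistic), 8)  # Welch t is near 10 at these moments

  # heavy-tailed data -> rank-sum branch
  withr::with_seed(65, cau <- rcauchy(60))
  gc2 <- group_compare(c(cau, cau + 0.2), rep(c(0, 1), each = 60))
  expect_equal(gc2$test, "wilcoxon")

  # identical duplicated groups -> rank-sum p near 1
  withr::with_seed(66, sk <- rexp(60)^2)
  gc3 <- group_compare(c(sk, sk), rep(c(0, 1), each = 60))
  expect_equal(gc3$test, "wilcoxon")
  expect_gt(gc3$p, 0.9)

  expect_error(group_compare(c(1, 1, 1, 2, 2, 2), c(0, 0, 0, 1, 1, 1)),
               "degenerate|constant")
  expect_error(group_compare(rnorm(4), c(0, 0, 1, 1)), "size >= 3")
})

test_that("chi-square on 2x2 tables matches the closed form", {
  even <- matrix(c(20, 10, 40, 20), 2)  # identical row proportions
  r <- chi_square_2x2(even)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # male counts by group in the emulated cohort: no sex difference
  sex_tab <- matrix(c(57, 30, 17, 9), 2)
  expect_gt(chi_square_2x2(sex_tab)$p, 0.05)
  # closed-form oracle n(ad - bc)^2 / (r1 r2 c1 c2)
  a <- 57; b <- 17; cc <- 30; d <- 9
  oracle <- (a + b + cc + d) * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(chi_square_2x2(sex_tab)$statistic, oracle, tolerance = 1e-12)

  diag_tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(chi_square_2x2(diag_tab)$statistic, 20, tolerance = 1e-12)
  expect_lt(chi_square_2x2(diag_tab)$p, 0.001)

  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2)), "marginal")
})

test_that("association table spans the consensus-by-test grid with per-test FDR", {
  cfg <- default_paper_config(seed = 6)
  co <- generate_cohort(cfg)
  feats <- cfg$planted_effects$feature
  tab <- association_table(co, feats)
  expect_s3_class(tab, "association_table")
  expect_equal(nrow(tab), 13 * 4)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
  expect_equal(unique(tab$n), 74)
  # FDR family is per cognitive test across features
  for (tst in unique(tab$test)) {
    sel <- tab$test == tst
    expect_equal(tab$p_fdr[sel], bh_fdr(tab$p_raw[sel]))
  }
  # planted ACR-FA/TMT-B association present and negative
  acr <- tab[tab$feature == "diffusion__FA__anterior_corona_radiata_R" &
               tab$test == "TMT_B", ]
  expect_lt(acr$r, 0)

  expect_error(association_table(co, character(0)), "empty")
  expect_error(association_table(co, "diffusion__FA__nowhere"), "not in cohort")
})
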