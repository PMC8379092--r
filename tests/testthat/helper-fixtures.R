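# Small programmatic fixtures shared across tests.

tiny_labels <- function(n_wm = 3, n_gm = 4) {
  list(wm = paste0("wm_region_", seq_len(n_wm)),
       gm = paste0("gm_region_", seq_len(n_gm)))
}

# A small synthetic cohort config: few features, optional planted effects.
tiny_config <- function(n_case = 24, n_control = 16, n_wm = 3, n_gm = 4,
                        d = NULL, seed = 1, ...) {
  lab <- tiny_labels(n_wm, n_gm)
  planted <- NULL
  if (!is.null(d)) {
    # plant a group difference on the first FA and the first CBF feature
    idx <- build_feature_index(lab$wm, lab$gm)
    f1 <- idx$name[idx$metric == "FA"][1]
    f2 <- idx$name[idx$metric == "CBF"][1]
    planted <- data.frame(feature = c(f1, f2),
                          mean_control = c(0.35, 50),
                          mean_case = c(0.35 - d * 0.03, 50 - d * 6),
                          sd = c(0.03, 6))
  }
  synthetic_config(n_case = n_case, n_control = n_control,
                   wm_labels = lab$wm, gm_labels = lab$gm,
                   planted_effects = planted, seed = seed, ...)
}

tiny_cohort <- function(..., seed = 1) generate_cohort(tiny_config(..., seed = seed))

# Deterministic matrix whose standardized columns are exactly orthonormal
# under the 1/n inner product (orthogonalized, centered and rescaled).
orthonormal_design <- function(n, p, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X <- sweep(X, 2L, colMeans(X))
    Q <- qr.Q(qr(X))
    Q <- sweep(Q, 2L, colMeans(Q))
    Q <- sweep(Q, 2L, sqrt(colSums(Q^2) / n), "/")
    Q
  })
}
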