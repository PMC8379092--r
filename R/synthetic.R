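# Synthetic cohort generation.
#
# The generator emulates the statistical structure the analysis assumes: a
# two-group (vMCI / control) cohort with atlas-wise diffusion and perfusion
# features, exchangeable within-modality background correlation, a configurable
# set of planted group mean differences, and cognitive scores built as linear
# combinations of covariates plus planted feature effects whose coefficients
# are solved analytically (jointly, accounting for inter-feature correlation)
# so that each planted (feature, test) pair has exactly the target partial
# correlation within the case group, conditional on sex/age/education.

# Per-metric baseline means and SDs on the reporting scales used throughout
# (FA unitless; MD/AD/RD on the 1e-4 mm^2/s scale; CBF in mL/100g/min).
METRIC_BASELINES <- data.frame(
  metric = c("FA", "MD", "AD", "RD", "CBF"),
  mean = c(0.40, 8.0, 13.0, 6.0, 45.0),
  sd = c(0.030, 0.80, 1.20, 0.80, 6.0),
  stringsAsFactors = FALSE
)

# Group-wise cognitive score distributions and shared covariate effects.
# Means/SDs follow the demographic table of the study population this
# generator emulates; covariate slopes are modest, clinically plausible values
# (timed tests worsen with age, improve with education).
COGNITIVE_MODEL <- data.frame(
  test = c("MoCA", "MMSE", "TMT_A", "TMT_B", "Stroop_CT", "VFT"),
  mean_case = c(21.72, 27.17, 99.18, 225.38, 126.40, 13.01),
  mean_control = c(26.33, 28.49, 59.46, 150.83, 79.26, 16.12),
  sd_case = c(3.43, 1.98, 50.60, 87.38, 56.94, 4.00),
  sd_control = c(1.23, 1.23, 15.10, 38.41, 15.36, 3.63),
  b_age = c(-0.06, -0.04, 1.0, 2.0, 1.0, -0.05),
  b_sex = c(0, 0, -3, -5, 0, 0),
  b_edu = c(0.2, 0.15, -1.5, -3.0, -1.5, 0.2),
  stringsAsFactors = FALSE
)

#' Configure a synthetic diffusion-perfusion cohort
#'
#' @param n_case,n_control Group sizes (vMCI cases / cognitively normal
#'   controls); defaults 74 and 39.
#' @param wm_labels,gm_labels Region label vocabularies; default to the
#'   packaged 48 ICBM-DTI-81 and 116 AAL lists (the 308-feature schema).
#' @param planted_effects Data frame with columns `feature` (encoded feature
#'   name), `mean_control`, `mean_case`, `sd` (common within-group SD). These
#'   features carry a true group difference; all other features have equal
#'   group means.
#' @param planted_associations Data frame with columns `feature`, `test`,
#'   `r`: target partial Pearson correlation (controlling sex/age/education)
#'   between the feature and the cognitive score within the case group.
#' @param background_sd Multiplier (> 0) on the per-metric baseline SDs of
#'   non-planted features; default 1.
#' @param rho Exchangeable within-modality background correlation in `[0, 1)`;
#'   default 0.3. Features of different modalities are independent.
#' @param p_male Probability of male sex, applied in both groups (default
#'   0.77, matching the heavily male study population).
#' @param age_case,age_control,education Length-2 `c(mean, sd)` vectors for the
#'   demographic distributions (normal, truncated at plausible bounds).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `synthetic_config` (a named list).
#' @seealso [default_paper_config()], [generate_cohort()]
#' @export
synthetic_config <- function(n_case = 74, n_control = 39,
                             wm_labels = icbm_dti81_labels(),
                             gm_labels = aal116_labels(),
                             planted_effects = NULL,
                             planted_associations = NULL,
                             background_sd = 1, rho = 0.3,
                             p_male = 0.77,
                             age_case = c(65.97, 6.84),
                             age_control = c(63.44, 7.04),
                             education = c(10.5, 2.6),
                             seed = 1L) {
  if (n_case < 2 || n_control < 2) stop("group sizes must be at least 2")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (background_sd <= 0) stop("background_sd must be positive")
  idx <- build_feature_index(wm_labels, gm_labels)
  if (!is.null(planted_effects)) {
    stopifnot(all(c("feature", "mean_control", "mean_case", "sd") %in%
                    names(planted_effects)))
    bad <- setdiff(planted_effects$feature, idx$name)
    if (length(bad)) stop("planted effect feature(s) not in index: ",
                          paste(bad, collapse = ", "))
    if (any(planted_effects$sd <= 0)) stop("planted effect SDs must be positive")
  }
  if (!is.null(planted_associations)) {
    stopifnot(all(c("feature", "test", "r") %in% names(planted_associations)))
    bad <- setdiff(planted_associations$feature, idx$name)
    if (length(bad)) stop("planted association feature(s) not in index: ",
                          paste(bad, collapse = ", "))
    bad_t <- setdiff(planted_associations$test, COGNITIVE_TESTS)
    if (length(bad_t)) stop("unknown cognitive test(s): ",
                            paste(bad_t, collapse = ", "))
    if (any(abs(planted_associations$r) >= 1))
      stop("target partial correlations must satisfy |r| < 1")
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    wm_labels = wm_labels, gm_labels = gm_labels, feature_index = idx,
    planted_effects = planted_effects,
    planted_associations = planted_associations,
    background_sd = background_sd, rho = rho, p_male = p_male,
    age_case = age_case, age_control = age_control, education = education,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default study-emulating configuration
#'
#' Plants the 13 discriminative features of the emulated study with their
#' published group means (8 CBF regions and 5 white-matter diffusion features,
#' e.g. right Rolandic operculum CBF 49.215 in cases vs 55.617 in controls,
#' right anterior corona radiata FA 0.316 vs 0.346) and the 7 significant
#' within-case feature-cognition partial correlations (e.g. right anterior
#' corona radiata FA vs TMT-B, target r = -0.404). Planted SDs are set so
#' every planted effect has Cohen's d equal to `d` (default 0.8).
#'
#' @param d Standardized effect size (Cohen's d) of the planted group
#'   differences.
#' @param seed Integer seed stored in the config.
#' @inheritParams synthetic_config
#' @return A `synthetic_config`.
#' @export
default_paper_config <- function(d = 0.8, seed = 1L, n_case = 74, n_control = 39) {
  if (d <= 0) stop("d must be positive")
  eff <- data.frame(
    feature = c(
      "perfusion__CBF__Rolandic_Oper_R",
      "perfusion__CBF__Supp_Motor_Area_R",
      "perfusion__CBF__Frontal_Sup_Medial_R",
      "perfusion__CBF__ParaHippocampal_L",
      "perfusion__CBF__ParaHippocampal_R",
      "perfusion__CBF__Caudate_R",
      "perfusion__CBF__Temporal_Sup_L",
      "perfusion__CBF__Cerebelum_4_5_R",
      "diffusion__FA__anterior_corona_radiata_R",
      "diffusion__AD__posterior_corona_radiata_R",
      "diffusion__FA__external_capsule_L",
      "diffusion__FA__superior_longitudinal_fasciculus_R",
      "diffusion__FA__uncinate_fasciculus_L"
    ),
    mean_case = c(49.215, 41.087, 37.611, 45.680, 44.219, 34.338, 51.629,
                  41.420, 0.316, 13.612, 0.328, 0.369, 0.336),
    mean_control = c(55.617, 48.511, 40.417, 50.681, 50.527, 35.348, 56.769,
                     43.792, 0.346, 13.125, 0.350, 0.380, 0.357),
    stringsAsFactors = FALSE
  )
  eff$sd <- abs(eff$mean_case - eff$mean_control) / d
  assoc <- data.frame(
    feature = c(
      "diffusion__AD__posterior_corona_radiata_R",
      "diffusion__FA__external_capsule_L",
      "diffusion__FA__anterior_corona_radiata_R",
      "diffusion__FA__external_capsule_L",
      "diffusion__FA__superior_longitudinal_fasciculus_R",
      "diffusion__AD__posterior_corona_radiata_R",
      "diffusion__FA__anterior_corona_radiata_R"
    ),
    test = c("TMT_A", "TMT_A", "TMT_B", "TMT_B", "TMT_B", "TMT_B", "VFT"),
    r = c(0.339, -0.361, -0.404, -0.359, -0.368, 0.391, 0.377),
    stringsAsFactors = FALSE
  )
  synthetic_config(n_case = n_case, n_control = n_control,
                   planted_effects = eff, planted_associations = assoc,
                   seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws demographics, correlated feature noise, planted group differences and
#' cognitive scores per the configuration. Deterministic given
#' `config$seed` (or the `seed` override).
#'
#' @param config A [synthetic_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An `svd_cohort`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed %||% config$seed)
  with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  idx <- config$feature_index
  n_case <- config$n_case
  n_ctrl <- config$n_control
  n <- n_case + n_ctrl
  p <- nrow(idx)

  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("S%0", width, "d"), seq_len(n))
  diagnosis <- c(rep(1L, n_case), rep(0L, n_ctrl))

  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, lo), hi)
  }
  sex <- stats::rbinom(n, 1L, config$p_male)
  age <- numeric(n)
  age[diagnosis == 1] <- rtrunc_norm(n_case, config$age_case[1], config$age_case[2], 45, 90)
  age[diagnosis == 0] <- rtrunc_norm(n_ctrl, config$age_control[1], config$age_control[2], 45, 90)
  education <- rtrunc_norm(n, config$education[1], config$education[2], 0, 22)

  # feature means/SDs per group
  base <- METRIC_BASELINES[match(idx$metric, METRIC_BASELINES$metric), ]
  mu_case <- base$mean
  mu_ctrl <- base$mean
  sd_j <- base$sd * config$background_sd
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    pos <- match(pe$feature, idx$name)
    mu_case[pos] <- pe$mean_case
    mu_ctrl[pos] <- pe$mean_control
    sd_j[pos] <- pe$sd
  }

  # exchangeable within-modality noise: z = sqrt(rho) g_modality + sqrt(1-rho) eps
  rho <- config$rho
  g_dif <- stats::rnorm(n)
  g_per <- stats::rnorm(n)
  g <- cbind(diffusion = g_dif, perfusion = g_per)[, idx$modality, drop = FALSE]
  eps <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(rho) * g + sqrt(1 - rho) * eps
  mu <- ifelse(diagnosis == 1, 1, 0) %o% mu_case +
    ifelse(diagnosis == 1, 0, 1) %o% mu_ctrl
  features <- mu + sweep(z, 2L, sd_j, `*`)
  dimnames(features) <- list(ids, idx$name)

  # cognitive scores: group mean + covariate effects + planted terms + noise
  cm <- COGNITIVE_MODEL
  is_case <- diagnosis == 1
  scores <- matrix(NA_real_, n, nrow(cm), dimnames = list(ids, cm$test))
  cov_part <- function(k) {
    cm$b_age[k] * (age - 64.8) + cm$b_sex[k] * (sex - config$p_male) +
      cm$b_edu[k] * (education - config$education[1])
  }
  pa <- config$planted_associations
  for (k in seq_len(nrow(cm))) {
    mean_k <- ifelse(is_case, cm$mean_case[k], cm$mean_control[k])
    sd_k <- ifelse(is_case, cm$sd_case[k], cm$sd_control[k])
    sc <- mean_k + cov_part(k) + stats::rnorm(n, 0, sd_k)
    if (!is.null(pa)) {
      rows <- pa[pa$test == cm$test[k], , drop = FALSE]
      if (nrow(rows)) {
        coefs <- solve_association_coefs(rows, idx, sd_j, rho,
                                         sigma_t = cm$sd_case[k])
        pos <- match(rows$feature, idx$name)
        centered <- sweep(features[is_case, pos, drop = FALSE], 2L,
                          mu_case[pos], `-`)
        sc[is_case] <- sc[is_case] + drop(centered %*% coefs)
      }
    }
    scores[, k] <- sc
  }

  phenotype <- data.frame(
    subject_id = ids, diagnosis = diagnosis, sex = sex,
    age = age, education = education,
    as.data.frame(scores), stringsAsFactors = FALSE
  )
  new_cohort(phenotype, features)
}

# Joint analytic solve for the planted-association coefficients of one test.
# With T = c'f + e, Var(e) = sigma^2, and feature covariance Sigma = D R D
# (R the exchangeable-within-modality correlation), requiring the partial
# correlation vector corr(T, f_k | covariates) = r gives
#   c = s * D^{-1} R^{-1} r,  s = sigma / sqrt(1 - r' R^{-1} r),
# which is feasible iff r' R^{-1} r < 1.
solve_association_coefs <- function(rows, idx, sd_j, rho, sigma_t) {
  pos <- match(rows$feature, idx$name)
  k <- length(pos)
  mod <- idx$modality[pos]
  R <- diag(k)
  if (k > 1) {
    same <- outer(mod, mod, `==`)
    R[same & !diag(k)] <- rho
  }
  r <- rows$r
  Rinv_r <- solve(R, r)
  q <- sum(r * Rinv_r)
  if (q >= 1)
    stop(sprintf("planted partial correlations for test '%s' are jointly infeasible (r'R^-1 r = %.3f >= 1)",
                 rows$test[1], q))
  s <- sigma_t / sqrt(1 - q)
  s * Rinv_r / sd_j[pos]
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d cases / %d controls, %d features\n",
              x$n_case, x$n_control, nrow(x$feature_index)))
  cat(sprintf("  planted effects: %d; planted associations: %d; rho = %.2f; seed = %d\n",
              if (is.null(x$planted_effects)) 0L else nrow(x$planted_effects),
              if (is.null(x$planted_associations)) 0L else nrow(x$planted_associations),
              x$rho, x$seed))
  invisible(x)
}
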