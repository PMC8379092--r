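# End-to-end orchestration: run the classifier on each requested modality
# subset, compare the combined model against the single-modality models with
# McNemar's test, tabulate demographics, and render report artifacts.

#' Pipeline configuration
#'
#' @param feature_path,phenotype_path Cohort files (see [load_cohort()]); when
#'   both are NULL the cohort is simulated from `synthetic`.
#' @param synthetic A [synthetic_config()] used when no files are given.
#' @param modalities Modality subsets to fit; the first is treated as the
#'   reference model for McNemar comparisons.
#' @param threshold Consensus frequency threshold.
#' @param lasso,logit Stage configurations.
#' @param tests Cognitive tests for the association analysis.
#' @param seed Global seed; fans out to per-stage seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_path = NULL, phenotype_path = NULL,
                            synthetic = default_paper_config(),
                            modalities = c("combined", "perfusion", "diffusion"),
                            threshold = 0.75,
                            lasso = lasso_config(), logit = logit_config(),
                            tests = c("TMT_A", "TMT_B", "Stroop_CT", "VFT"),
                            seed = 1L) {
  modalities <- match.arg(modalities, c("combined", "perfusion", "diffusion"),
                          several.ok = TRUE)
  structure(list(feature_path = feature_path, phenotype_path = phenotype_path,
                 synthetic = synthetic, modalities = modalities,
                 threshold = threshold, lasso = lasso, logit = logit,
                 tests = tests, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a cohort, fits [nested_slr()] for every requested
#' modality subset, compares the first (reference) model against each other
#' model with [mcnemar_compare()], computes the demographics table with
#' normality-gated group tests, and runs the feature-cognition association
#' analysis on the reference model's consensus features within the vMCI
#' group. Deterministic given the configuration: identical configs and seeds
#' yield identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `svd_cohort` overriding the config's
#'   cohort source.
#' @return An object of class `slr_run`: `cohort`, `fits` (named list of
#'   `nested_slr`), `metrics` (one row per modality: accuracy, sensitivity,
#'   specificity, AUC), `mcnemar` (named list), `demographics`,
#'   `associations` (or NULL if the reference consensus set is empty),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$feature_path) || !is.null(config$phenotype_path)) {
      load_cohort(config$feature_path, config$phenotype_path)
    } else {
      generate_cohort(config$synthetic, seed = derive_seed(config$seed, "simulate"))
    }
  }
  fits <- lapply(config$modalities, function(m)
    nested_slr(cohort, m, threshold = config$threshold,
               lasso = config$lasso, logit = config$logit,
               seed = derive_seed(config$seed, paste0("fit_", m))))
  names(fits) <- config$modalities

  metrics <- do.call(rbind, lapply(config$modalities, function(m) {
    f <- fits[[m]]
    data.frame(model = m, accuracy = f$metrics$accuracy,
               sensitivity = f$metrics$sensitivity,
               specificity = f$metrics$specificity,
               auc = f$roc$auc, stringsAsFactors = FALSE)
  }))

  ref <- config$modalities[1]
  truth <- fits[[ref]]$loocv$predictions$y
  mcn <- list()
  for (m in setdiff(config$modalities, ref)) {
    mcn[[paste(ref, "vs", m)]] <- mcnemar_compare(
      fits[[ref]]$loocv$predictions$pred,
      fits[[m]]$loocv$predictions$pred, truth)
  }

  demographics <- demographics_table(cohort)

  associations <- NULL
  if (length(fits[[ref]]$consensus$consensus) &&
      all(config$tests %in% names(cohort$phenotype))) {
    associations <- association_table(cohort, fits[[ref]]$consensus,
                                      tests = config$tests, group = "vMCI")
  }
  structure(list(cohort = cohort, fits = fits, metrics = metrics,
                 mcnemar = mcn, demographics = demographics,
                 associations = associations, config = config),
            class = "slr_run")
}

# Demographic/cognitive comparison table: normality-gated tests for the
# continuous variables, chi-square for sex.
demographics_table <- function(cohort) {
  ph <- cohort$phenotype
  vars <- intersect(c("age", "education", COGNITIVE_TESTS), names(ph))
  rows <- lapply(vars, function(v) {
    gc <- group_compare(ph[[v]], ph$diagnosis)
    data.frame(
      variable = v,
      vMCI = sprintf("%.2f ± %.2f", mean(ph[[v]][ph$diagnosis == 1]),
                     stats::sd(ph[[v]][ph$diagnosis == 1])),
      control = sprintf("%.2f ± %.2f", mean(ph[[v]][ph$diagnosis == 0]),
                        stats::sd(ph[[v]][ph$diagnosis == 0])),
      test = gc$test, p = gc$p, stringsAsFactors = FALSE)
  })
  sex_tab <- table(factor(ph$diagnosis, c(1, 0)), factor(ph$sex, c(1, 0)))
  cs <- chi_square_2x2(sex_tab)
  rows <- c(list(data.frame(
    variable = "sex_male",
    vMCI = sprintf("%d (%.1f%%)", sum(ph$sex == 1 & ph$diagnosis == 1),
                   100 * mean(ph$sex[ph$diagnosis == 1] == 1)),
    control = sprintf("%d (%.1f%%)", sum(ph$sex == 1 & ph$diagnosis == 0),
                      100 * mean(ph$sex[ph$diagnosis == 0] == 1)),
    test = "chi-square", p = cs$p, stringsAsFactors = FALSE)), rows)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.slr_run <- function(x, ...) {
  cat("Diffusion-perfusion discrimination pipeline\n")
  print(x$cohort)
  cat("\nModel metrics (LOOCV):\n")
  print(x$metrics, row.names = FALSE)
  if (length(x$mcnemar)) {
    cat("\nPaired comparisons:\n")
    for (nm in names(x$mcnemar))
      cat(sprintf("  %s: p = %.4g (%s)\n", nm, x$mcnemar[[nm]]$p,
                  x$mcnemar[[nm]]$method))
  }
  if (!is.null(x$associations))
    cat(sprintf("\nAssociations: %d records, %d significant at FDR < 0.05\n",
                nrow(x$associations), sum(x$associations$significant)))
  invisible(x)
}

#' Render report artifacts for a pipeline run
#'
#' Writes human-readable and machine-readable summaries: `report.txt`
#' (demographics with group tests, model metrics, consensus feature table
#' with frequencies, group means and group-test p-values, association grid),
#' `metrics.csv`, `consensus_<modality>.csv`, `roc_<modality>.csv` per model,
#' `associations.csv`, and `run.json` with every seed and penalty used. An
#' empty consensus set renders an explicit "no consensus features" section.
#'
#' @param run An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(run, dir) {
  stopifnot(inherits(run, "slr_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wpath <- function(f) file.path(dir, f)

  utils::write.csv(run$metrics, wpath("metrics.csv"), row.names = FALSE)
  paths <- c(paths, wpath("metrics.csv"))
  for (m in names(run$fits)) {
    f <- run$fits[[m]]
    utils::write.csv(f$roc$points, wpath(paste0("roc_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(consensus_report_table(run$cohort, f),
                     wpath(paste0("consensus_", m, ".csv")), row.names = FALSE)
    paths <- c(paths, wpath(paste0("roc_", m, ".csv")),
               wpath(paste0("consensus_", m, ".csv")))
  }
  if (!is.null(run$associations)) {
    utils::write.csv(as.data.frame(run$associations),
                     wpath("associations.csv"), row.names = FALSE)
    paths <- c(paths, wpath("associations.csv"))
  }

  art <- list(
    seed = run$config$seed,
    modalities = run$config$modalities,
    metrics = run$metrics,
    mcnemar = lapply(run$mcnemar, function(m) m[c("b", "c", "statistic", "p", "method")]),
    pool_lambdas = lapply(run$fits, function(f) f$loocv$pool_lambda),
    reduced_sets = lapply(run$fits, function(f)
      lapply(f$reduced$pools, function(p) p[c("pool", "features")]))
  )
  jsonlite::write_json(art, wpath("run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, wpath("run.json"))

  rep <- c("Diffusion-perfusion vMCI discrimination report", "",
           "== Demographics ==",
           utils::capture.output(print(run$demographics, row.names = FALSE)),
           "", "== Model metrics (LOOCV) ==",
           utils::capture.output(print(run$metrics, row.names = FALSE)))
  for (nm in names(run$mcnemar))
    rep <- c(rep, sprintf("McNemar %s: b = %d, c = %d, p = %.4g (%s)", nm,
                          run$mcnemar[[nm]]$b, run$mcnemar[[nm]]$c,
                          run$mcnemar[[nm]]$p, run$mcnemar[[nm]]$method))
  for (m in names(run$fits)) {
    f <- run$fits[[m]]
    rep <- c(rep, "", sprintf("== Consensus features (%s) ==", m))
    if (length(f$consensus$consensus) == 0L) {
      rep <- c(rep, "No consensus features reached the frequency threshold.")
    } else {
      rep <- c(rep, utils::capture.output(
        print(consensus_report_table(run$cohort, f), row.names = FALSE)))
    }
  }
  if (!is.null(run$associations)) {
    rep <- c(rep, "", "== Feature-cognition associations (vMCI group) ==",
             utils::capture.output(print(as.data.frame(run$associations),
                                         row.names = FALSE)))
  }
  writeLines(rep, wpath("report.txt"))
  paths <- c(paths, wpath("report.txt"))
  invisible(paths)
}

# Consensus table in reporting shape: frequency, type (metric), region, group
# means, and the group-comparison p-value per feature.
consensus_report_table <- function(cohort, fit) {
  cs <- fit$consensus
  feats <- cs$consensus
  if (length(feats) == 0L)
    return(data.frame(frequency = numeric(0), type = character(0),
                      region = character(0), vMCI = numeric(0),
                      control = numeric(0), p = numeric(0)))
  idx <- cohort$feature_index[match(feats, cohort$feature_index$name), ]
  y <- cohort$phenotype$diagnosis
  rows <- lapply(seq_along(feats), function(i) {
    v <- cohort$features[, feats[i]]
    data.frame(frequency = cs$table$frequency[match(feats[i], cs$table$feature)],
               type = idx$metric[i], region = idx$region[i],
               vMCI = mean(v[y == 1]), control = mean(v[y == 0]),
               p = group_compare(v, y)$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$frequency), ]
  rownames(out) <- NULL
  out
}
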