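#' @useDynLib nestedSLR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef predict
NULL

DIFFUSION_METRICS <- c("FA", "MD", "AD", "RD")
COGNITIVE_TESTS <- c("MoCA", "MMSE", "TMT_A", "TMT_B", "Stroop_CT", "VFT")
PHENOTYPE_CORE <- c("subject_id", "diagnosis", "sex", "age", "education")

#' Packaged atlas label vocabularies
#'
#' The 48 ICBM-DTI-81 white-matter labels and the 116 AAL gray-matter labels
#' ship with the package as plain-text lists so the full 308-feature schema is
#' constructible offline.
#'
#' @return Character vector of region labels.
#' @export
icbm_dti81_labels <- function() {
  read_label_file(system.file("extdata", "icbm_dti81_labels.txt",
                              package = "nestedSLR", mustWork = TRUE))
}

#' @rdname icbm_dti81_labels
#' @export
aal116_labels <- function() {
  read_label_file(system.file("extdata", "aal116_labels.txt",
                              package = "nestedSLR", mustWork = TRUE))
}

read_label_file <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Build the atlas-wise feature index
#'
#' Constructs the ordered feature index used throughout the pipeline: for each
#' white-matter label, four diffusion metrics (FA, MD, AD, RD, in that fixed
#' order), followed by one CBF perfusion feature per gray-matter label. With
#' the packaged vocabularies this yields the 308-feature schema
#' (48 x 4 = 192 diffusion + 116 perfusion features).
#'
#' Feature columns are named `modality__metric__region` with double-underscore
#' separators, e.g. `diffusion__FA__anterior_corona_radiata_R`.
#'
#' @param wm_labels Character vector of white-matter (ICBM-DTI-81) region
#'   labels; may be empty.
#' @param gm_labels Character vector of gray-matter (AAL) region labels; may
#'   be empty.
#' @return A data frame with columns `name`, `modality`, `metric`, `region`,
#'   `atlas`, one row per feature, in deterministic order.
#' @examples
#' idx <- build_feature_index(icbm_dti81_labels(), aal116_labels())
#' nrow(idx)  # 308
#' @export
build_feature_index <- function(wm_labels, gm_labels) {
  wm_labels <- as.character(wm_labels)
  gm_labels <- as.character(gm_labels)
  if (anyDuplicated(wm_labels)) stop("duplicate white-matter labels in feature index")
  if (anyDuplicated(gm_labels)) stop("duplicate gray-matter labels in feature index")
  if (length(wm_labels) + length(gm_labels) == 0L)
    stop("feature index needs at least one label")
  dif <- if (length(wm_labels)) {
    data.frame(
      modality = "diffusion",
      metric = rep(DIFFUSION_METRICS, times = length(wm_labels)),
      region = rep(wm_labels, each = length(DIFFUSION_METRICS)),
      atlas = "ICBM_DTI_81",
      stringsAsFactors = FALSE
    )
  } else NULL
  per <- if (length(gm_labels)) {
    data.frame(
      modality = "perfusion", metric = "CBF", region = gm_labels,
      atlas = "AAL", stringsAsFactors = FALSE
    )
  } else NULL
  idx <- rbind(dif, per)
  idx$name <- paste(idx$modality, idx$metric, idx$region, sep = "__")
  idx <- idx[, c("name", "modality", "metric", "region", "atlas")]
  rownames(idx) <- NULL
  idx
}

# Parse encoded column names back into an index data frame; errors on any
# malformed name or on a metric/modality/atlas combination that violates the
# schema (CBF <=> perfusion <=> AAL; FA/MD/AD/RD <=> diffusion <=> ICBM).
parse_feature_names <- function(names) {
  parts <- strsplit(names, "__", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 3L, logical(1))
  if (any(bad))
    stop("unparseable feature column header(s): ",
         paste(names[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  modality <- vapply(parts, `[[`, "", 1L)
  metric <- vapply(parts, `[[`, "", 2L)
  region <- vapply(parts, `[[`, "", 3L)
  ok <- (modality == "diffusion" & metric %in% DIFFUSION_METRICS) |
    (modality == "perfusion" & metric == "CBF")
  if (!all(ok))
    stop("feature name(s) violate the modality/metric schema: ",
         paste(names[!ok][seq_len(min(3, sum(!ok)))], collapse = ", "))
  if (anyDuplicated(paste(metric, region)))
    stop("duplicate (metric, region) pairs in feature index")
  data.frame(
    name = names, modality = modality, metric = metric, region = region,
    atlas = ifelse(modality == "diffusion", "ICBM_DTI_81", "AAL"),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated cohort
#'
#' Binds a phenotype table to a subjects-by-features matrix, validates both
#' against the schema, and sorts subjects by `subject_id` so that all
#' downstream computation is independent of input row order.
#'
#' @param phenotype Data frame with columns `subject_id`, `diagnosis`
#'   (1 = vMCI, 0 = control), `sex` (0/1), `age`, `education`, and optionally
#'   the cognitive score columns `MoCA`, `MMSE`, `TMT_A`, `TMT_B`,
#'   `Stroop_CT`, `VFT` (present as a set or absent as a set).
#' @param features Numeric matrix, one row per subject (rownames =
#'   `subject_id`), columns named `modality__metric__region`.
#' @return An object of class `svd_cohort`: a list with elements `phenotype`,
#'   `features` and `feature_index`.
#' @export
new_cohort <- function(phenotype, features) {
  stopifnot(is.data.frame(phenotype))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  missing_cols <- setdiff(PHENOTYPE_CORE, names(phenotype))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  have_cog <- intersect(COGNITIVE_TESTS, names(phenotype))
  if (length(have_cog) && !setequal(have_cog, COGNITIVE_TESTS))
    stop("cognitive score columns must be present as a complete set; missing: ",
         paste(setdiff(COGNITIVE_TESTS, have_cog), collapse = ", "))
  if (nrow(phenotype) == 0L) stop("cohort has no subjects")
  phenotype$subject_id <- as.character(phenotype$subject_id)
  if (anyDuplicated(phenotype$subject_id)) stop("duplicate subject_id in phenotype")
  if (!all(phenotype$diagnosis %in% c(0, 1)))
    stop("diagnosis must be coded 0 (control) / 1 (vMCI)")
  if (!all(phenotype$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (any(phenotype$age < 0) || any(phenotype$education < 0))
    stop("age and education must be non-negative")

  if (is.null(rownames(features))) stop("feature matrix needs subject_id rownames")
  if (!setequal(rownames(features), phenotype$subject_id))
    stop("subject_id mismatch between phenotype and feature tables: ",
         paste(c(setdiff(rownames(features), phenotype$subject_id),
                 setdiff(phenotype$subject_id, rownames(features)))[1:3],
               collapse = ", "))
  idx <- parse_feature_names(colnames(features))
  if (anyNA(features)) {
    w <- which(is.na(features), arr.ind = TRUE)[1, ]
    stop(sprintf("missing feature value for subject '%s', feature '%s' (no imputation)",
                 rownames(features)[w[1]], colnames(features)[w[2]]))
  }
  num_cols <- setdiff(names(phenotype), "subject_id")
  if (anyNA(phenotype[num_cols])) {
    bad <- which(colSums(is.na(phenotype[num_cols])) > 0)[1]
    stop("missing phenotype value in column '", num_cols[bad], "' (no imputation)")
  }

  ord <- order(phenotype$subject_id)
  phenotype <- phenotype[ord, , drop = FALSE]
  rownames(phenotype) <- NULL
  features <- features[phenotype$subject_id, , drop = FALSE]
  structure(list(phenotype = phenotype, features = features, feature_index = idx),
            class = "svd_cohort")
}

#' Read a cohort from feature and phenotype tables
#'
#' Both files are delimited text (TSV by default, CSV if the file extension is
#' `.csv`), UTF-8, decimal point. The feature table's first column must be
#' `subject_id` and the remaining column headers must follow the
#' `modality__metric__region` convention. Rows are aligned across the two
#' files by `subject_id`; a subject present in only one file, an unparseable
#' header, or any missing numeric cell is an error (the pipeline analyses
#' complete cases only and never imputes).
#'
#' @param feature_path,phenotype_path Paths to the two tables.
#' @return A validated [new_cohort()] object.
#' @export
load_cohort <- function(feature_path, phenotype_path) {
  for (p in c(feature_path, phenotype_path))
    if (!file.exists(p)) stop("file not found: ", p)
  fx <- read_table_auto(feature_path)
  ph <- read_table_auto(phenotype_path)
  if (names(fx)[1] != "subject_id")
    stop("feature table's first column must be 'subject_id' (", feature_path, ")")
  if (!"subject_id" %in% names(ph))
    stop("phenotype table lacks 'subject_id' (", phenotype_path, ")")
  mat <- as.matrix(fx[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    notnum <- names(fx)[-1][!vapply(fx[-1], is.numeric, logical(1))][1]
    bad_row <- which(is.na(suppressWarnings(as.numeric(fx[[notnum]]))))[1]
    stop(sprintf("non-numeric/missing feature value for subject '%s', feature '%s'",
                 fx$subject_id[bad_row %||% 1], notnum))
  }
  rownames(mat) <- as.character(fx$subject_id)
  only_f <- setdiff(rownames(mat), as.character(ph$subject_id))
  only_p <- setdiff(as.character(ph$subject_id), rownames(mat))
  if (length(only_f) || length(only_p))
    stop("subject(s) present in one file only: ",
         paste(c(only_f, only_p)[seq_len(min(3, length(only_f) + length(only_p)))],
               collapse = ", "))
  new_cohort(ph, mat)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""),
                    fileEncoding = "UTF-8")
}

#' Write a cohort to feature and phenotype tables
#'
#' Inverse of [load_cohort()]: numeric values are written with 17 significant
#' digits so that a load/write round trip reproduces the cohort exactly.
#'
#' @param cohort An `svd_cohort`.
#' @param feature_path,phenotype_path Output paths (`.csv` extension writes
#'   CSV, anything else TSV).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, feature_path, phenotype_path) {
  stopifnot(inherits(cohort, "svd_cohort"))
  if (nrow(cohort$phenotype) == 0L) stop("refusing to write an empty cohort")
  write_one <- function(df, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    ok <- try(utils::write.table(df, path, sep = sep, quote = FALSE,
                                 row.names = FALSE, fileEncoding = "UTF-8"),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write '", path, "': ", attr(ok, "condition")$message)
  }
  fx <- data.frame(subject_id = rownames(cohort$features),
                   cohort$features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_one(fx, feature_path)
  write_one(cohort$phenotype, phenotype_path)
  invisible(c(feature_path, phenotype_path))
}

#' Restrict a cohort to one imaging modality
#'
#' @param cohort An `svd_cohort`.
#' @param modality `"combined"` (all 308 features), `"diffusion"` (FA/MD/AD/RD
#'   over white-matter labels) or `"perfusion"` (CBF over gray-matter labels).
#' @return An `svd_cohort` with the restricted feature index.
#' @export
subset_modality <- function(cohort, modality = c("combined", "diffusion", "perfusion")) {
  modality <- match.arg(modality)
  if (modality == "combined") return(cohort)
  keep <- cohort$feature_index$modality == modality
  if (!any(keep)) stop("no features of modality '", modality, "' in cohort")
  cohort$features <- cohort$features[, keep, drop = FALSE]
  cohort$feature_index <- cohort$feature_index[keep, , drop = FALSE]
  rownames(cohort$feature_index) <- NULL
  cohort
}

#' @export
print.svd_cohort <- function(x, ...) {
  ph <- x$phenotype
  cat(sprintf("Cohort: %d subjects (%d vMCI, %d control), %d features (%d diffusion, %d perfusion)\n",
              nrow(ph), sum(ph$diagnosis == 1), sum(ph$diagnosis == 0),
              nrow(x$feature_index),
              sum(x$feature_index$modality == "diffusion"),
              sum(x$feature_index$modality == "perfusion")))
  if (all(COGNITIVE_TESTS %in% names(ph)))
    cat("Cognitive scores:", paste(COGNITIVE_TESTS, collapse = ", "), "\n")
  invisible(x)
}
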