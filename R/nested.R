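# 10x10 nested feature selection: the cohort is split into 10 outer folds
# stratified by (diagnosis, sex); for each outer fold, the lasso is run on 10
# inner folds of the remaining subjects and the per-inner-fold supports are
# combined by union. Each outer fold's members form a "testing pool" whose
# LOOCV iterations all share that pool's reduced feature set, so no subject
# ever contributes to the selection of the features used to predict it.

# Deal stratum members round-robin into folds, starting each stratum at the
# currently smallest folds, so per-stratum and global fold sizes both differ
# by at most 1. Assumes the RNG is already seeded (call under with_seed()).
make_strat_folds <- function(keys, k) {
  n <- length(keys)
  if (k > n) stop("more folds than observations")
  fold <- integer(n)
  sizes <- integer(k)
  tab <- sort(table(keys), decreasing = TRUE)
  for (s in names(tab)) {
    members <- which(keys == s)
    members <- members[sample.int(length(members))]
    ord <- order(sizes, seq_len(k))
    slots <- ord[((seq_along(members) - 1L) %% k) + 1L]
    fold[members] <- slots
    sizes <- sizes + tabulate(slots, k)
  }
  fold
}

#' Stratified k-fold split
#'
#' Splits subjects into `k` folds stratified by (diagnosis, sex) so that every
#' fold holds a near-equal share of each diagnosis-by-sex combination: within
#' each stratum per-fold counts differ by at most 1, and so do total fold
#' sizes. Strata smaller than `k` are spread round-robin after a seeded
#' shuffle. Randomness is keyed to sorted `subject_id` plus the seed, so input
#' row order cannot change the assignment.
#'
#' @param phenotype Phenotype data frame (needs `subject_id`, `diagnosis`,
#'   `sex`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of class `fold_assignment`: `assignment` (named integer
#'   vector, subject_id -> fold), `n_folds`, `seed`.
#' @export
stratified_kfold <- function(phenotype, k = 10, seed = 1L) {
  stopifnot(k >= 2)
  if (k > nrow(phenotype)) stop("k exceeds cohort size")
  ord <- order(phenotype$subject_id)
  ids <- phenotype$subject_id[ord]
  keys <- paste(phenotype$diagnosis[ord], phenotype$sex[ord], sep = ":")
  fold <- with_seed(seed, make_strat_folds(keys, k))
  names(fold) <- ids
  structure(list(assignment = fold, n_folds = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

# Restrict a cohort to a subject subset (by id), keeping feature columns.
cohort_rows <- function(cohort, ids) {
  keep <- cohort$phenotype$subject_id %in% ids
  cohort$phenotype <- cohort$phenotype[keep, , drop = FALSE]
  cohort$features <- cohort$features[keep, , drop = FALSE]
  cohort
}

#' Inner-loop union feature selection
#'
#' Splits the given subjects into 10 stratified inner folds; for each inner
#' fold, fits a cross-validated-lambda lasso of the diagnosis label on the
#' features of that fold's training portion (the other nine folds) and records
#' its selected support. The ten supports are combined by union, so a feature
#' important for any subsample of the training data is retained. An inner fit
#' that selects nothing contributes the empty set.
#'
#' @param cohort An `svd_cohort` (the outer-training subjects).
#' @param config A [lasso_config()].
#' @param seed Integer seed (inner folds and per-fit CV).
#' @param n_inner Number of inner folds (default 10).
#' @return A list with `features` (character union), and `inner` (data frame
#'   per inner fold: `fold`, `lambda`, `n_selected`).
#' @export
inner_union_selection <- function(cohort, config = lasso_config(), seed = 1L,
                                  n_inner = 10) {
  ph <- cohort$phenotype
  if (length(unique(ph$diagnosis)) < 2)
    stop("subset must contain both classes")
  fa <- stratified_kfold(ph, k = n_inner, seed = derive_seed(seed, "inner_folds"))
  fold <- fa$assignment[ph$subject_id]
  y <- ph$diagnosis
  sel <- vector("list", n_inner)
  info <- data.frame(fold = seq_len(n_inner), lambda = NA_real_,
                     n_selected = NA_integer_)
  for (f in seq_len(n_inner)) {
    tr <- fold != f
    ytr <- y[tr]
    if (length(unique(ytr)) < 2)
      stop("inner fold ", f, ": training portion has a single class")
    Xtr <- cohort$features[tr, , drop = FALSE]
    keep <- apply(Xtr, 2L, function(col) stats::var(col) > 0)
    cv <- cv_select_lambda(Xtr[, keep, drop = FALSE], ytr, config,
                           seed = derive_seed(seed, paste0("inner_cv_", f)))
    fit <- lasso_fit(Xtr[, keep, drop = FALSE], ytr, cv$lambda_star, config)
    sel[[f]] <- fit$support
    info$lambda[f] <- cv$lambda_star
    info$n_selected[f] <- length(fit$support)
  }
  list(features = sort(unique(unlist(sel))), inner = info)
}

#' Nested 10x10 feature selection
#'
#' Runs [inner_union_selection()] on the training side of each of `n_outer`
#' stratified outer folds. Each outer fold's members are kept as a testing
#' pool; all leave-one-out iterations for subjects of a pool share that pool's
#' reduced feature set, which was computed without any of them.
#'
#' @param cohort An `svd_cohort` with both classes present.
#' @param config A [lasso_config()].
#' @param seed Integer seed (fans out deterministically to outer folds and
#'   inner selections).
#' @param n_outer,n_inner Outer/inner fold counts (default 10 each).
#' @return An object of class `reduced_feature_sets`: list with `pools` (one
#'   element per outer fold: `pool` subject ids, `train` the subject ids the
#'   reduced set was computed from -- recorded so the no-leak property is
#'   machine-checkable -- `features` reduced set, `inner` per-inner-fold
#'   audit), `fold_assignment` and `seed`.
#' @export
nested_fs <- function(cohort, config = lasso_config(), seed = 1L,
                      n_outer = 10, n_inner = 10) {
  ph <- cohort$phenotype
  if (length(unique(ph$diagnosis)) < 2) stop("cohort must contain both classes")
  fa <- stratified_kfold(ph, k = n_outer, seed = derive_seed(seed, "outer_folds"))
  pools <- vector("list", n_outer)
  for (f in seq_len(n_outer)) {
    pool_ids <- names(fa$assignment)[fa$assignment == f]
    train_ids <- setdiff(ph$subject_id, pool_ids)
    sel <- inner_union_selection(cohort_rows(cohort, train_ids), config,
                                 seed = derive_seed(seed, paste0("outer_", f)),
                                 n_inner = n_inner)
    pools[[f]] <- list(pool = sort(pool_ids), train = sort(train_ids),
                       features = sel$features, inner = sel$inner)
  }
  structure(list(pools = pools, fold_assignment = fa, seed = as.integer(seed)),
            class = "reduced_feature_sets")
}

#' @export
print.reduced_feature_sets <- function(x, ...) {
  sizes <- vapply(x$pools, function(p) length(p$features), integer(1))
  cat(sprintf("Nested feature selection: %d testing pools; reduced-set sizes %s\n",
              length(x$pools), paste(sizes, collapse = "/")))
  invisible(x)
}

# which pool a subject belongs to
pool_of <- function(reduced, subject_id) {
  for (i in seq_along(reduced$pools))
    if (subject_id %in% reduced$pools[[i]]$pool) return(i)
  stop("subject '", subject_id, "' not covered by any testing pool")
}
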