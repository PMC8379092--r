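test_that("feature index has the atlas-wise layout and fixed metric order", {
  idx <- build_feature_index(icbm_dti81_labels(), aal116_labels())
  expect_equal(nrow(idx), 308)
  expect_equal(sum(idx$modality == "diffusion"), 192)
  expect_equal(sum(idx$modality == "perfusion"), 116)
  expect_false(anyDuplicated(paste(idx$metric, idx$region)) > 0)

  only_wm <- build_feature_index(icbm_dti81_labels(), character(0))
  expect_equal(nrow(only_wm), 192)
  expect_true(all(only_wm$modality == "diffusion"))

  one_each <- build_feature_index("acr", "hippocampus")
  expect_equal(one_each$metric, c("FA", "MD", "AD", "RD", "CBF"))
  expect_equal(one_each$name[1], "diffusion__FA__acr")
  expect_equal(one_each$atlas, c(rep("ICBM_DTI_81", 4), "AAL"))
})

test_that("feature index length is 4*|wm| + |gm| and order is stable", {
  for (nw in c(1, 5, 48)) {
    for (ng in c(0, 3, 116)) {
      idx <- build_feature_index(paste0("w", seq_len(nw)),
                                 if (ng) paste0("g", seq_len(ng)) else character(0))
      expect_equal(nrow(idx), 4 * nw + ng)
    }
  }
  a <- build_feature_index(c("b_region", "a_region"), "gm1")
  b <- build_feature_index(c("b_region", "a_region"), "gm1")
  expect_identical(a, b)  # no hash-order dependence
})

test_that("schema violations are rejected", {
  expect_error(build_feature_index(c("a", "a"), "g"), "duplicate")
  expect_error(build_feature_index("a", c("g", "g")), "duplicate")
  expect_error(nestedSLR:::parse_feature_names("diffusion__CBF__region"), "schema")
  expect_error(nestedSLR:::parse_feature_names("perfusion__FA__region"), "schema")
  expect_error(nestedSLR:::parse_feature_names("just_a_name"), "unparseable")
})

test_that("cohort load/write round trip is the identity", {
  co <- tiny_cohort(n_case = 6, n_control = 5)
  fp <- tempfile(fileext = ".tsv")
  pp <- tempfile(fileext = ".tsv")
  write_cohort(co, fp, pp)
  co2 <- load_cohort(fp, pp)
  expect_identical(co2$features, co$features)
  expect_equal(co2$phenotype, co$phenotype)
  expect_identical(co2$feature_index, co$feature_index)

  # CSV flavour too
  fpc <- tempfile(fileext = ".csv")
  ppc <- tempfile(fileext = ".csv")
  write_cohort(co, fpc, ppc)
  expect_identical(load_cohort(fpc, ppc)$features, co$features)
})

test_that("loading rejects misaligned, missing or malformed inputs", {
  co <- tiny_cohort(n_case = 6, n_control = 5)
  fp <- tempfile(fileext = ".tsv"); pp <- tempfile(fileext = ".tsv")
  write_cohort(co, fp, pp)

  # drop one subject from the phenotype file only -> alignment error
  ph <- read.delim(pp, check.names = FALSE)
  write.table(ph[-1, ], pp2 <- tempfile(fileext = ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(fp, pp2), "one file only")

  # NA feature cell -> validation error naming subject and feature
  fx <- read.delim(fp, check.names = FALSE)
  fx[2, 3] <- "NA"
  write.table(fx, fp2 <- tempfile(fileext = ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  err <- tryCatch(load_cohort(fp2, pp), error = conditionMessage)
  expect_match(err, fx$subject_id[2], fixed = TRUE)
  expect_match(err, names(fx)[3], fixed = TRUE)

  # malformed header
  names(fx)[2] <- "notaname"
  write.table(fx, fp3 <- tempfile(fileext = ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(fp3, pp))

  expect_error(load_cohort("nope.tsv", pp), "not found")
})

test_that("cohort validation enforces the phenotype contract", {
  co <- tiny_cohort(n_case = 5, n_control = 5)
  ph <- co$phenotype
  ph$diagnosis[1] <- 2
  expect_error(new_cohort(ph, co$features), "diagnosis")
  ph <- co$phenotype
  ph$age[2] <- -1
  expect_error(new_cohort(ph, co$features), "non-negative")
  ph <- co$phenotype
  ph$MoCA <- NULL  # cognitive columns must come as a set
  expect_error(new_cohort(ph, co$features), "complete set")
  expect_error(write_cohort(structure(list(phenotype = ph[0, ], features = co$features),
                                      class = "svd_cohort"),
                            tempfile(), tempfile()), "empty")
})

test_that("subject row order never matters", {
  co <- tiny_cohort(n_case = 8, n_control = 6)
  perm <- rev(seq_len(nrow(co$phenotype)))
  co_shuffled <- new_cohort(co$phenotype[perm, ], co$features[perm, ])
  expect_identical(co_shuffled$features, co$features)
  expect_equal(co_shuffled$phenotype, co$phenotype)
})

test_that("modality subsetting restricts the index", {
  co <- tiny_cohort()
  dif <- subset_modality(co, "diffusion")
  expect_true(all(dif$feature_index$modality == "diffusion"))
  expect_equal(ncol(dif$features), sum(co$feature_index$modality == "diffusion"))
  expect_identical(subset_modality(co, "combined"), co)
})
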