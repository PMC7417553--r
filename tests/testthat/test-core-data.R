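test_that("layout validation enforces unique, non-empty feature sets", {
  expect_s3_class(tiny_layout(), "dataset_layout")
  expect_error(
    dataset_layout(list(a = list(s1 = c("x", "y"), s2 = "x")), 5),
    "unique"
  )
  expect_error(
    dataset_layout(list(a = list(s1 = character(0))), 5),
    "at least one feature"
  )
  lay <- tiny_layout()
  expect_equal(layout_n_features(lay),
               sum(layout_submodalities(lay)$n_features))
})

test_that("manifest round-trip preserves values, mask and layout", {
  fx <- write_tiny_manifest()
  ds <- load_dataset(fx$manifest)
  expect_equal(length(ds$blocks), 2L)
  expect_equal(dim(ds$blocks$memory), c(10L, 3L))
  expect_equal(ds$blocks, fx$dataset$blocks)
  expect_equal(extract_missing_mask(ds)$masks,
               extract_missing_mask(fx$dataset)$masks)
  expect_equal(layout_submodalities(ds$layout),
               layout_submodalities(fx$dataset$layout))
  expect_equal(ds$outcomes$label, fx$dataset$outcomes$label)
  unlink(fx$dir, recursive = TRUE)
})

test_that("loading errors name the offending block or column", {
  fx <- write_tiny_manifest()
  # drop a declared feature column from one block CSV
  bpath <- file.path(fx$dir, "tiny_block_memory.csv")
  df <- read.csv(bpath, check.names = FALSE)
  write.csv(df[, setdiff(names(df), "rt_mean")], bpath, row.names = FALSE)
  expect_error(load_dataset(fx$manifest), "rt_mean")
  # duplicate a subject id
  write.csv(df, bpath, row.names = FALSE, na = "")
  opath <- file.path(fx$dir, "tiny_outcomes.csv")
  od <- read.csv(opath)
  od$subject_id[2] <- od$subject_id[1]
  write.csv(od, opath, row.names = FALSE, na = "")
  expect_error(load_dataset(fx$manifest), "duplicated subject_id")
  unlink(fx$dir, recursive = TRUE)
})

test_that("the mask flags exactly the punched holes", {
  fx <- write_tiny_manifest()
  ds <- load_dataset(fx$manifest)
  mask <- extract_missing_mask(ds)
  expect_true(mask$masks$memory[4L, "rt_mean"])
  expect_equal(sum(unlist(mask$masks)), 1L)
  expect_equal(unname(mask$fractions[["memory"]]), 1 / 30)
  expect_equal(unname(mask$fractions[["volume"]]), 0)
  unlink(fx$dir, recursive = TRUE)
})

test_that("fully observed data gives an all-false mask; extraction is idempotent", {
  ds <- tiny_cohort()
  mask <- extract_missing_mask(ds)
  expect_false(any(unlist(mask$masks)))
  expect_equal(unname(mask$fractions), c(0, 0))
  # re-apply then re-extract: identical mask
  ds2 <- apply_missing_pattern(ds, mask)
  expect_equal(extract_missing_mask(ds2), mask)
})

test_that("block-wise missingness yields the expected per-block fraction", {
  ds <- tiny_cohort(n = 10L)
  ds$blocks$volume[c(2L, 5L, 8L), ] <- NA
  frac <- extract_missing_mask(ds)$fractions
  expect_equal(unname(frac[["volume"]]), 0.3)
})

test_that("split then concatenate reconstructs the feature matrix", {
  ds <- tiny_cohort(n = 20L, seed = 9L)
  subs <- split_into_submodalities(ds)
  expect_equal(length(subs), 2L)
  feats <- lapply(subs, function(s) {
    s$block[, colnames(ds$blocks[[s$name]]), drop = FALSE]
  })
  rebuilt <- do.call(cbind, unname(feats))
  full <- do.call(cbind, unname(ds$blocks))
  expect_equal(rebuilt, full)
  # covariates appended to every block
  covn <- colnames(covariate_matrix(ds))
  for (s in subs) {
    expect_true(all(covn %in% colnames(s$block)))
  }
})

test_that("single-submodality layout splits to the whole table plus covariates", {
  lay <- dataset_layout(list(m = list(only = c("a", "b", "c"))), 15)
  ds <- tiny_cohort(n = 15L, layout = lay)
  subs <- split_into_submodalities(ds)
  expect_equal(length(subs), 1L)
  expect_equal(ncol(subs$only$block),
               3L + ncol(covariate_matrix(ds)))
  expect_equal(subs$only$block[, c("a", "b", "c")], ds$blocks$only)
})

test_that("covariate one-hot encoding is deterministic and numeric", {
  ds <- tiny_cohort(n = 30L, seed = 4L)
  cm <- covariate_matrix(ds)
  expect_true(is.numeric(cm))
  expect_true("age" %in% colnames(cm))
  expect_true(any(grepl("^sex_", colnames(cm))))
  # indicator columns are 0/1
  ind <- cm[, grepl("^(sex|cohort|handedness)_", colnames(cm)), drop = FALSE]
  expect_true(all(ind %in% c(0, 1)))
})
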