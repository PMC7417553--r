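test_that("cluster latent is two-point and balanced at default mixing", {
  lay <- tiny_layout()
  spec <- latent_cohort_spec("cluster", 1e4, 0, lay, seed = 2L)
  z <- sample_latent(spec)
  expect_true(all(abs(z) == 1))
  expect_gt(mean(z), -0.05)
  expect_lt(mean(z), 0.05)
})

test_that("spectrum latent matches a standard normal within 3 SE", {
  lay <- tiny_layout()
  spec <- latent_cohort_spec("spectrum", 1e4, 0, lay, seed = 3L)
  z <- sample_latent(spec)
  expect_lt(abs(mean(z)), 3 / sqrt(1e4))
  # SE of the sample variance of N(0,1) is sqrt(2/n)
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / 1e4))
})

test_that("latent sampling and cohort generation are seed-deterministic", {
  lay <- tiny_layout()
  spec <- latent_cohort_spec("cluster", 100, 5, lay, seed = 7L)
  expect_identical(sample_latent(spec), sample_latent(spec))
  d1 <- generate_cohort(spec)
  d2 <- generate_cohort(spec)
  expect_equal(d1$blocks, d2$blocks)
  expect_equal(d1$outcomes, d2$outcomes)
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(generate_cohort(spec2)$blocks$memory,
                         d1$blocks$memory))
})

test_that("realized signal/noise variance ratio hits the dB target within 1%", {
  lay <- tiny_layout()
  for (snr in c(0, 20, -10)) {
    spec <- latent_cohort_spec("spectrum", 200, snr, lay, seed = 5L)
    ds <- generate_cohort(spec)
    z <- ds$meta$latent
    w <- unlist(lapply(random_loadings(lay, 5L), `[[`, "w"))
    signal <- outer(z, unname(w))
    full <- do.call(cbind, unname(ds$blocks))
    noise <- full - signal
    ratio <- var(as.vector(signal)) / var(as.vector(noise))
    expect_gt(ratio / 10^(snr / 10), 0.99)
    expect_lt(ratio / 10^(snr / 10), 1.01)
  }
})

test_that("at -20 dB no single feature separates the cluster labels", {
  lay <- tiny_layout()
  spec <- latent_cohort_spec("cluster", 300, -20, lay, seed = 9L)
  ds <- generate_cohort(spec)
  z <- ds$meta$latent
  full <- do.call(cbind, unname(ds$blocks))
  r_obs <- abs(cor(full, z))
  # permutation null for the max point-biserial correlation per feature
  set.seed(1)
  null_max <- replicate(200, max(abs(cor(full, sample(z)))))
  expect_true(all(r_obs <= quantile(null_max, 0.999) + 0.05))
})

test_that("outcome links follow their definitions", {
  expect_equal(derive_outcomes(c(-1, -1, 1), "cluster_label")$label,
               c(0, 0, 1))
  z <- rnorm(100)
  expect_equal(sum(derive_outcomes(z, "binary_threshold")$label), 50)
  expect_error(derive_outcomes(z, "nonsense"), "unknown outcome link")
  expect_error(derive_outcomes(numeric(0), "cluster_label"), "non-empty")
  # linear response at 20 dB: R^2 = SNR/(SNR+1) = 100/101
  z <- with(list(), {set.seed(11); rnorm(1e4)})
  resp <- derive_outcomes(z, "linear_response", seed = 1L, snr_db = 20)$response
  expect_equal(cor(resp, z)^2, 100 / 101, tolerance = 0.005)
})

test_that("missingness grafting reproduces the template exactly", {
  ds <- tiny_cohort(n = 10L, seed = 3L)
  mask <- extract_missing_mask(ds) # all-false
  expect_equal(apply_missing_pattern(ds, mask)$blocks, ds$blocks)
  # block-wise holes for subjects 2 and 5
  mask$masks$volume[c(2L, 5L), ] <- TRUE
  out <- apply_missing_pattern(ds, mask)
  expect_true(all(is.na(out$blocks$volume[c(2L, 5L), ])))
  expect_equal(out$blocks$volume[-c(2L, 5L), ], ds$blocks$volume[-c(2L, 5L), ])
  expect_equal(out$blocks$memory, ds$blocks$memory)
  expect_equal(extract_missing_mask(out)$fractions,
               vapply(mask$masks, mean, numeric(1)))
})

test_that("mask transfer resamples rows when subject counts differ", {
  template <- tiny_cohort(n = 20L, seed = 3L)
  template$blocks$memory[1:10, 1L] <- NA
  mask <- extract_missing_mask(template)
  ds <- tiny_cohort(n = 35L, seed = 4L, layout = tiny_layout(35L))
  out <- apply_missing_pattern(ds, mask, seed = 6L)
  expect_equal(nrow(out$blocks$memory), 35L)
  # resampled rows preserve the column pattern: holes only in column 1
  expect_true(all(!is.na(out$blocks$memory[, 2:3])))
})

test_that("grid cardinality is the product of its axis lengths", {
  lay <- tiny_layout()
  base <- latent_cohort_spec("cluster", 20, 0, lay, seed = 1L)
  expect_equal(nrow(grid_cells(grid_spec(base))), 180L)
  g1 <- grid_spec(base, snr_values = 0, variants = "cluster", seeds = 1L)
  expect_equal(length(build_grid(g1)), 1L)
  g12 <- grid_spec(base, snr_values = c(-5, 5), seeds = 1:3)
  ds <- build_grid(g12)
  expect_equal(length(ds), 12L)
  cells <- vapply(ds, function(d) paste(d$meta$cell, collapse = "|"),
                  character(1))
  expect_equal(anyDuplicated(cells), 0L)
})

test_that("the reference fixture mirrors the cohort shape", {
  fx <- reference_fixture(seed = 1L)
  expect_equal(length(fx$layout$modalities), 5L)
  expect_equal(fx$layout$n_subjects, 289L)
  expect_setequal(names(fx$layout$modalities),
                  c("cognition", "MRI", "electrophysiology",
                    "psychopathology", "perinatal_register"))
  # deterministic
  fx2 <- reference_fixture(seed = 1L)
  expect_equal(fx$mask$masks, fx2$mask$masks)
  expect_equal(fx$loadings, fx2$loadings)
  # both block-wise rows and scattered holes present
  m <- fx$mask$masks$cortical_LH
  expect_true(any(rowSums(m) == ncol(m)))
  expect_true(any(rowSums(m) > 0 & rowSums(m) < ncol(m)))
})
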