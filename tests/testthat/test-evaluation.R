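test_that("balanced accuracy matches per-class recall arithmetic", {
  expect_equal(balanced_accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(
    balanced_accuracy(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 0)),
    (3 / 4 + 1 / 2) / 2
  )
  expect_error(balanced_accuracy(c(1, 1), c(1, 0)), "both classes")
  # invariance under swapping class labels in both vectors
  set.seed(1)
  yt <- rbinom(50, 1, 0.3); yp <- rbinom(50, 1, 0.5)
  expect_equal(balanced_accuracy(yt, yp), balanced_accuracy(1 - yt, 1 - yp))
})

test_that("NMSE uses the population-variance convention", {
  expect_equal(nmse(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(nmse(c(0, 1, 2), c(0, 0, 0)), (5 / 3) / (2 / 3))
  y <- rnorm(30)
  expect_equal(nmse(y, rep(mean(y), 30)), 1) # mean predictor = chance
  expect_error(nmse(rep(2, 5), rnorm(5)), "constant")
  # invariance under a common affine map
  yp <- rnorm(30)
  expect_equal(nmse(3 * y + 2, 3 * yp + 2), nmse(y, yp))
})

test_that("score summaries reproduce degenerate and percentile intervals", {
  s <- summarize_scores(rep(0.5, 10), 0.5, "higher")
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci, c(0.5, 0.5))
  expect_false(s$significant)
  s1 <- summarize_scores(rep(1, 10), 0.5, "higher")
  expect_equal(s1$ci, c(1, 1))
  expect_true(s1$significant)
  # percentile CI against a direct order-statistic interpolation oracle
  x <- seq(0.40, 0.90, length.out = 100)
  s2 <- summarize_scores(x, 0.5, "higher")
  oracle <- function(p) {
    h <- (100 - 1) * p + 1 # R type-7 plotting position
    xs <- sort(x)
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, 100)] - xs[lo])
  }
  expect_equal(s2$ci, c(oracle(0.025), oracle(0.975)))
})

test_that("paired sign-flip test behaves at its extremes and matches enumeration", {
  a <- rep(0.7, 20)
  expect_equal(compare_algorithms(a, a), 1)
  expect_lte(compare_algorithms(rep(0.9, 100), rep(0.5, 100)), 0.001)
  # n = 10: Monte-Carlo p within MC error of exhaustive enumeration
  set.seed(4)
  d <- rnorm(10, mean = 0.4, sd = 0.5)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  exact <- mean(abs(signs %*% d) / 10 >= obs - 1e-12)
  mc <- compare_algorithms(d, rep(0, 10), n_perm = 10000L, seed = 2L)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 10000) + 2e-4)
})

test_that("late integration averages only the available submodalities", {
  p <- rbind(c(0.2, 0.8, 0.8), c(0.4, 0.4, 0.4))
  expect_equal(late_integrate(p, "mean"), c(0.6, 0.4))
  expect_equal(hard_labels(late_integrate(p, "mean")), c(1, 0))
  # identical predictions across submodalities integrate to themselves
  q <- matrix(0.3, 4, 3)
  expect_equal(late_integrate(q, "mean"), rep(0.3, 4))
  # one block missing: average over the two available
  r <- rbind(c(NA, 0.9, 0.5))
  expect_equal(late_integrate(r, "mean"), 0.7)
  # weighted: weights renormalized over available blocks
  expect_equal(late_integrate(r, "weighted", weights = c(5, 3, 1)),
               (0.9 * 3 + 0.5 * 1) / 4)
  expect_error(late_integrate(rbind(c(NA, NA)), "mean"),
               "no available submodality")
  expect_equal(late_integrate(rbind(c(NA, NA)), "mean", fallback = 0.5), 0.5)
})

test_that("outer splits are 75/25 with stratification within one subject", {
  lay <- tiny_layout(100L)
  ds <- tiny_cohort(n = 100L, snr_db = 0, seed = 21L, layout = lay)
  # unbalance the labels: cluster with mixing 0.4
  spec <- latent_cohort_spec("cluster", 100, 0, lay, "cluster_label",
                             mixing_proportion = 0.4, seed = 21L)
  ds <- generate_cohort(spec)
  reg <- classification_registry()
  res <- outer_cv(ds, reg$cart_default, "classification",
                  cv = outer_cv_spec(n_replications = 4L, seed = 9L))
  pos_rate <- mean(ds$outcomes$label)
  for (rep in res$replications) {
    expect_length(rep$test_ids, 25L)
    pos_test <- sum(ds$outcomes$label[ds$subject_ids %in% rep$test_ids])
    expect_lte(abs(pos_test - 25 * pos_rate), 1)
  }
})

test_that("a constant-majority predictor scores BACC 0.5 with CI [0.5, 0.5]", {
  ds <- tiny_cohort(n = 80L, snr_db = 0, seed = 13L,
                    layout = tiny_layout(80L))
  # a root-only decision tree always predicts the training majority class
  stump <- simguided:::algorithm_config(
    "stump", "classification", "decision_tree", "rpart",
    fixed = list(cp = 1, minsplit = 1000))
  res <- outer_cv(ds, stump, "classification",
                  cv = outer_cv_spec(n_replications = 6L, seed = 3L))
  expect_equal(res$scores, rep(0.5, 6L))
  expect_equal(res$summary$ci, c(0.5, 0.5))
  expect_false(res$summary$significant)
})

test_that("ranking selects best, lower-middle median and poorest", {
  mk <- function(ids, scores) {
    data.frame(config_id = rep(ids, each = 2),
               snr_db = rep(c(-10, -5), length(ids)),
               score = rep(scores, each = 2))
  }
  r3 <- rank_algorithms(mk(c("a", "b", "c"), c(0.7, 0.6, 0.5)))
  expect_equal(r3$best, "a")
  expect_equal(r3$median, "b")
  expect_equal(r3$poorest, "c")
  r1 <- rank_algorithms(mk("only", 0.6))
  expect_equal(c(r1$best, r1$median, r1$poorest), rep("only", 3))
  # even count: lower-middle order statistic
  r4 <- rank_algorithms(mk(c("p", "q", "r", "s"), c(0.9, 0.8, 0.7, 0.6)))
  expect_equal(r4$median, "r")
  # error-like scores rank in reverse
  r4e <- rank_algorithms(mk(c("p", "q", "r", "s"), c(0.9, 0.8, 0.7, 0.6)),
                         better = "lower")
  expect_equal(r4e$best, "s")
  expect_equal(r4e$median, "q") # lower-middle in quality order
  expect_equal(r4e$poorest, "p")
  # SNR window actually filters
  gr <- data.frame(config_id = c("a", "a", "b", "b"),
                   snr_db = c(-10, 20, -10, 20),
                   score = c(0.5, 1.0, 0.6, 0.6))
  expect_equal(rank_algorithms(gr, snr_window = c(-20, 0))$best, "b")
})

test_that("validate_ranking requires selections and attaches p-values", {
  bogus <- structure(list(best = NULL), class = "ranking_report")
  ds <- tiny_cohort(n = 60L, seed = 2L, layout = tiny_layout(60L))
  expect_error(validate_ranking(bogus, ds), "selections")
  gr <- data.frame(config_id = rep(c("logreg_default", "cart_default",
                                     "nb_default"), each = 1),
                   snr_db = -5, score = c(0.7, 0.6, 0.65))
  rep <- rank_algorithms(gr)
  out <- validate_ranking(rep, ds, task = "classification",
                          cv = outer_cv_spec(n_replications = 4L, seed = 5L))
  expect_length(out$transfer$means, 3L)
  expect_true(all(out$transfer$p_values >= 0 & out$transfer$p_values <= 1))
  expect_type(out$transfer$ranking_preserved, "logical")
})

test_that("no-leakage: perturbing test rows leaves fitted digests unchanged", {
  ds <- tiny_cohort(n = 60L, snr_db = 5, seed = 31L,
                    layout = tiny_layout(60L))
  ds$blocks$memory[2L, 1L] <- NA # some real missingness
  reg <- classification_registry()
  cv1 <- outer_cv_spec(n_replications = 1L, seed = 17L)
  r1 <- outer_cv(ds, reg$logreg_default, "classification", cv = cv1,
                 collect_digests = TRUE)
  test_ids <- r1$replications[[1L]]$test_ids
  ds2 <- ds
  rows <- ds$subject_ids %in% test_ids
  for (b in names(ds2$blocks)) {
    ds2$blocks[[b]][rows, ] <- ds2$blocks[[b]][rows, ] * 5 + 100
  }
  r2 <- outer_cv(ds2, reg$logreg_default, "classification", cv = cv1,
                 collect_digests = TRUE)
  expect_identical(r1$replications[[1L]]$digests,
                   r2$replications[[1L]]$digests)
  # and the predictions DO change, so the digests are not vacuous
  expect_false(identical(r1$replications[[1L]]$integrated,
                         r2$replications[[1L]]$integrated))
})
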