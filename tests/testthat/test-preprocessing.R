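test_that("median imputation uses per-feature training medians", {
  X <- cbind(a = c(1, 2, 100, NA), b = c(0, NA, 4, 8))
  imp <- fit_imputer(X, "median")
  expect_equal(unname(imp$medians), c(2, 4))
  out <- apply_imputer(imp, X)
  expect_equal(unname(out[4L, "a"]), 2)
  expect_equal(unname(out[2L, "b"]), 4)
  expect_equal(out[1:3, "a"], X[1:3, "a"]) # observed entries untouched
  expect_false(anyNA(out))
  # idempotence: re-fitting on the completed block gives the same medians
  expect_equal(fit_imputer(out, "median")$medians, imp$medians)
})

test_that("imputation refuses features with no observed training value", {
  X <- cbind(a = c(NA, NA, NA), b = c(1, 2, 3))
  expect_error(fit_imputer(X, "median"), "a")
  expect_error(fit_imputer(X, "ppca"), "a")
})

test_that("a block with no missing entries passes through unchanged", {
  b <- rank1_block(n = 30L, p = 6L)$X
  imp <- fit_imputer(b, "median")
  expect_identical(apply_imputer(imp, b), b)
})

test_that("ppca with k = rank reconstructs a fully observed low-rank block", {
  set.seed(2)
  n <- 40L; p <- 8L; k <- 2L
  X <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * p), k, p)
  colnames(X) <- paste0("f", 1:p)
  imp <- fit_imputer(X, "ppca", k = k, max_iter = 2000L, tol = 1e-12)
  recon <- sweep(tcrossprod(
    t(apply(X, 1L, function(x) {
      M <- crossprod(imp$W) + diag(imp$sigma2, k)
      as.vector(chol2inv(chol(M)) %*% crossprod(imp$W, x - imp$mu))
    })), imp$W), 2L, imp$mu, "+")
  expect_lt(sqrt(mean((recon - X)^2)) / sqrt(mean(X^2)), 1e-3)
})

test_that("ppca imputes rank-1 data with holes close to truth at high SNR", {
  rb <- rank1_block(n = 60L, p = 12L, snr_db = 20, seed = 1L)
  set.seed(3)
  holes <- matrix(runif(60 * 12) < 0.1, 60L, 12L)
  Xm <- rb$X; Xm[holes] <- NA
  imp <- fit_imputer(Xm, "ppca", k = 1L)
  comp <- apply_imputer(imp, Xm)
  # error measured against the noise-free rank-1 signal; oracle is the SVD
  # rank-1 reconstruction of the complete noisy matrix
  sv <- svd(rb$X)
  oracle <- sv$d[1L] * outer(sv$u[, 1L], sv$v[, 1L])
  rms_ppca <- sqrt(mean((comp[holes] - rb$signal[holes])^2))
  rms_oracle <- sqrt(mean((oracle[holes] - rb$signal[holes])^2))
  signal_rms <- sqrt(mean(rb$signal[holes]^2))
  expect_lt(rms_ppca, 0.05 * signal_rms)
  expect_lt(rms_ppca, 3 * rms_oracle + 0.05 * signal_rms)
  # monotone EM
  expect_false(is.unsorted(imp$loglik_trace))
})

test_that("ppca beats median imputation on low-rank data across seeds", {
  wins <- vapply(1:10, function(s) {
    rb <- rank1_block(n = 50L, p = 10L, snr_db = 10, seed = s)
    set.seed(s + 100L)
    holes <- matrix(runif(500) < 0.1, 50L, 10L)
    if (!any(holes)) return(0)
    Xm <- rb$X; Xm[holes] <- NA
    pp <- apply_imputer(fit_imputer(Xm, "ppca", k = 1L), Xm)
    md <- apply_imputer(fit_imputer(Xm, "median"), Xm)
    sqrt(mean((md[holes] - rb$X[holes])^2)) -
      sqrt(mean((pp[holes] - rb$X[holes])^2))
  }, numeric(1))
  expect_gt(mean(wins), 0) # PPCA error <= median error on average
})

test_that("standardization uses training parameters only", {
  tr <- cbind(f = c(0, 2), g = c(1, 5))
  std <- fit_standardizer(tr)
  expect_equal(unname(std$mean), c(1, 3))
  expect_equal(unname(std$sd), c(sqrt(2), sqrt(8)))
  te <- cbind(f = 3, g = 3)
  expect_equal(unname(apply_standardizer(std, te)[1L, ]),
               c((3 - 1) / sqrt(2), 0))
  # self-standardized training block: mean 0, sd 1
  tr2 <- rank1_block(n = 30L, p = 4L)$X
  z <- apply_standardizer(fit_standardizer(tr2), tr2)
  expect_equal(unname(colMeans(z)), rep(0, 4L))
  expect_equal(unname(apply(z, 2L, sd)), rep(1, 4L))
})

test_that("zero-variance training features are centered, not scaled", {
  tr <- cbind(const = rep(3, 5), var = 1:5)
  std <- fit_standardizer(tr)
  expect_equal(unname(std$sd[["const"]]), 1)
  out <- apply_standardizer(std, tr)
  expect_equal(unname(out[, "const"]), rep(0, 5))
})

test_that("fitted preprocessing parameters ignore non-training rows", {
  rb <- rank1_block(n = 40L, p = 6L, seed = 5L)
  X <- rb$X
  X[3L, 2L] <- NA
  imp1 <- fit_imputer(X[1:30, ], "median")
  std1 <- fit_standardizer(apply_imputer(imp1, X[1:30, ]))
  # perturb the would-be test rows arbitrarily
  X[31:40, ] <- 1e6
  imp2 <- fit_imputer(X[1:30, ], "median")
  std2 <- fit_standardizer(apply_imputer(imp2, X[1:30, ]))
  expect_identical(param_digest(imp1), param_digest(imp2))
  expect_identical(param_digest(std1), param_digest(std2))
})
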