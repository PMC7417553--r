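# Probabilistic PCA with missing data, fitted by EM.
#
# Model: x_i = W z_i + mu + eps_i, z_i ~ N(0, I_k), eps_i ~ N(0, sigma2 I_p).
# Missing entries are marginalized out of the likelihood (each row contributes
# only through its observed coordinates), so imputation is the posterior mean
# E[x_mis | x_obs]. The mean vector is folded into the loading matrix via a
# constant latent component, which makes each M-step an exact joint update of
# (W, mu) and guarantees the observed-data log-likelihood never decreases.

ppca_loglik <- function(X, obs, W, mu, sigma2) {
  k <- ncol(W)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    o <- obs[i, ]
    d <- sum(o)
    if (d == 0L) next
    Wo <- W[o, , drop = FALSE]
    xo <- X[i, o] - mu[o]
    M <- crossprod(Wo) + diag(sigma2, k)
    # log|C| and x'C^{-1}x via Woodbury with C = Wo Wo' + sigma2 I_d
    cM <- chol(M)
    logdetC <- (d - k) * log(sigma2) + 2 * sum(log(diag(cM)))
    Wx <- crossprod(Wo, xo)
    quad <- (sum(xo^2) - sum(backsolve(cM, Wx, transpose = TRUE)^2)) / sigma2
    ll <- ll - 0.5 * (d * log(2 * pi) + logdetC + quad)
  }
  ll
}

fit_ppca_em <- function(X, k, max_iter = 500L, tol = 1e-6, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0L)) {
    stop("feature(s) with no observed training values: ",
         paste(colnames(X)[colSums(obs) == 0L], collapse = ", "))
  }
  stopifnot(k >= 1L, k < p)
  mu <- apply(X, 2L, mean, na.rm = TRUE)
  Xc <- sweep(X, 2L, mu)
  Xc[!obs] <- 0
  # initialize W from the SVD of the mean-imputed, centered data
  init <- with_seed(seed, {
    sv <- svd(Xc, nu = 0L, nv = k)
    d <- sv$d[seq_len(k)] / sqrt(max(n - 1L, 1L))
    sv$v %*% diag(d + 1e-6, k) +
      matrix(stats::rnorm(p * k, sd = 1e-8), p, k)
  })
  W <- init
  sigma2 <- max(mean((Xc[obs])^2) * 0.5, 1e-8)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: posterior of z_i given the observed coordinates of row i
    Ez <- matrix(0, n, k)
    sumEzz <- vector("list", n)
    for (i in seq_len(n)) {
      o <- obs[i, ]
      if (!any(o)) {
        sumEzz[[i]] <- diag(1, k)
        next
      }
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(sigma2, k)
      Minv <- chol2inv(chol(M))
      Ez[i, ] <- Minv %*% crossprod(Wo, X[i, o] - mu[o])
      sumEzz[[i]] <- sigma2 * Minv + tcrossprod(Ez[i, ])
    }
    # M-step: joint update of [W mu] by regressing each feature on (z, 1)
    Wnew <- matrix(0, p, k); munew <- numeric(p)
    for (j in seq_len(p)) {
      rows <- which(obs[, j])
      A <- matrix(0, k + 1L, k + 1L)
      b <- numeric(k + 1L)
      Szz <- Reduce(`+`, sumEzz[rows])
      Sz <- colSums(Ez[rows, , drop = FALSE])
      A[seq_len(k), seq_len(k)] <- Szz
      A[k + 1L, seq_len(k)] <- Sz
      A[seq_len(k), k + 1L] <- Sz
      A[k + 1L, k + 1L] <- length(rows)
      b[seq_len(k)] <- crossprod(Ez[rows, , drop = FALSE], X[rows, j])
      b[k + 1L] <- sum(X[rows, j])
      beta <- tryCatch(solve(A, b),
                       error = function(e) solve(A + diag(1e-10, k + 1L), b))
      Wnew[j, ] <- beta[seq_len(k)]
      munew[j] <- beta[k + 1L]
    }
    # sigma2 from expected residual sum of squares over observed entries
    rss <- 0; n_obs <- 0
    for (i in seq_len(n)) {
      o <- obs[i, ]
      if (!any(o)) next
      Wo <- Wnew[o, , drop = FALSE]
      r <- X[i, o] - mu_o_pred(Wo, munew[o], Ez[i, ])
      S <- sumEzz[[i]] - tcrossprod(Ez[i, ])
      rss <- rss + sum(r^2) + sum(diag(Wo %*% S %*% t(Wo)))
      n_obs <- n_obs + sum(o)
    }
    W <- Wnew; mu <- munew
    sigma2 <- max(rss / n_obs, 1e-12)

    ll <- ppca_loglik(X, obs, W, mu, sigma2)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(W = W, mu = mu, sigma2 = sigma2, k = k, n_iter = length(ll_trace),
       converged = converged, loglik_trace = ll_trace)
}

mu_o_pred <- function(Wo, muo, z) as.vector(Wo %*% z) + muo

ppca_impute_row <- function(x, W, mu, sigma2) {
  o <- !is.na(x)
  if (all(o)) return(x)
  k <- ncol(W)
  if (!any(o)) {
    x[] <- mu
    return(x)
  }
  Wo <- W[o, , drop = FALSE]
  M <- crossprod(Wo) + diag(sigma2, k)
  z <- chol2inv(chol(M)) %*% crossprod(Wo, x[o] - mu[o])
  x[!o] <- as.vector(W[!o, , drop = FALSE] %*% z) + mu[!o]
  x
}

#' Fit an imputer on training rows only
#'
#' Two methods, mirroring the bias comparison the framework is built for:
#' per-feature median of the observed training values, or probabilistic PCA
#' (PPCA) fitted by EM with missing entries marginalized out of the
#' likelihood. All parameters derive exclusively from the rows passed in, so
#' fitting on a training split can never see test data.
#'
#' @param train_block numeric matrix (training rows x features), `NA` =
#'   missing. Every feature needs at least one observed value.
#' @param method `"median"` or `"ppca"`.
#' @param k PPCA latent dimension; default `min(5, ncol - 1)`.
#' @param max_iter,tol EM stopping rule: stop when the relative change in
#'   observed-data log-likelihood drops below `tol`, or after `max_iter`
#'   iterations (the result is then flagged unconverged, with the iteration
#'   count).
#' @param seed integer seed controlling the EM start.
#' @return object of class `imputer_params` (serializable via
#'   [imputer_to_json()]).
#' @export
fit_imputer <- function(train_block, method = c("median", "ppca"),
                        k = NULL, max_iter = 500L, tol = 1e-6, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.matrix(train_block))
  obs_per_feat <- colSums(!is.na(train_block))
  if (any(obs_per_feat == 0L)) {
    stop("feature(s) with no observed training values: ",
         paste(colnames(train_block)[obs_per_feat == 0L], collapse = ", "))
  }
  if (method == "median") {
    med <- apply(train_block, 2L, stats::median, na.rm = TRUE)
    out <- list(method = "median", medians = med,
                features = colnames(train_block))
  } else {
    if (is.null(k)) k <- min(5L, ncol(train_block) - 1L)
    fit <- fit_ppca_em(train_block, k = k, max_iter = max_iter, tol = tol,
                       seed = seed)
    out <- c(list(method = "ppca", features = colnames(train_block)), fit)
  }
  structure(out, class = "imputer_params")
}

#' Apply a fitted imputer to a block
#'
#' Missing entries are replaced — by the training medians, or by the PPCA
#' posterior mean conditional on that row's observed entries. Observed
#' entries are returned unchanged and no missing flags remain.
#'
#' @param params an `imputer_params` from [fit_imputer()].
#' @param block numeric matrix with the same features as at fit time.
#' @return completed numeric matrix.
#' @export
apply_imputer <- function(params, block) {
  stopifnot(inherits(params, "imputer_params"), is.matrix(block))
  if (!identical(colnames(block), params$features)) {
    stop("block features do not match the fitted imputer")
  }
  if (!anyNA(block)) return(block)
  if (params$method == "median") {
    for (j in seq_len(ncol(block))) {
      miss <- is.na(block[, j])
      block[miss, j] <- params$medians[j]
    }
  } else {
    for (i in seq_len(nrow(block))) {
      if (anyNA(block[i, ])) {
        block[i, ] <- ppca_impute_row(block[i, ], params$W, params$mu,
                                      params$sigma2)
      }
    }
  }
  block
}

#' Serialize imputer parameters to JSON
#'
#' Makes every fitted parameter auditable, which is what the leakage audit
#' digests: two fits that saw the same training rows must serialize
#' identically regardless of test-set content.
#'
#' @param params an `imputer_params`.
#' @return JSON string.
#' @export
imputer_to_json <- function(params) {
  keep <- intersect(names(params),
                    c("method", "features", "medians", "W", "mu", "sigma2",
                      "k", "n_iter", "converged"))
  as.character(jsonlite::toJSON(params[keep], auto_unbox = TRUE, digits = NA))
}
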