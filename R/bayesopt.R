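# Sequential model-based optimization with expected improvement over a
# Gaussian-process surrogate on the unit hypercube. The first evaluation is
# always the declared default configuration, a fixed fraction of iterations
# explore at random, and the remainder maximize EI over a random candidate
# pool. Everything is deterministic given the seed.

space_encode <- function(hyper, space) {
  vapply(names(space), function(pn) {
    sp <- space[[pn]]
    v <- hyper[[pn]]
    if (sp$log) {
      (log(v) - log(sp$lower)) / (log(sp$upper) - log(sp$lower))
    } else {
      (v - sp$lower) / (sp$upper - sp$lower)
    }
  }, numeric(1))
}

space_decode <- function(u, space) {
  out <- lapply(seq_along(space), function(j) {
    sp <- space[[j]]
    v <- if (sp$log) {
      exp(log(sp$lower) + u[j] * (log(sp$upper) - log(sp$lower)))
    } else {
      sp$lower + u[j] * (sp$upper - sp$lower)
    }
    if (sp$type == "integer") v <- round(v)
    min(max(v, sp$lower), sp$upper)
  })
  names(out) <- names(space)
  out
}

space_defaults <- function(space) lapply(space, `[[`, "default")

# GP posterior (squared-exponential kernel, fixed lengthscale on the unit
# cube, small nugget) at candidate points; returns mean and sd.
gp_posterior <- function(U, y, Ucand, lengthscale = 0.3) {
  sf2 <- stats::var(y)
  if (!is.finite(sf2) || sf2 <= 0) sf2 <- 1e-8
  nug <- 1e-6 * sf2 + 1e-12
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  K <- sf2 * exp(-sqd(U, U) / (2 * lengthscale^2)) + diag(nug, nrow(U))
  Ks <- sf2 * exp(-sqd(Ucand, U) / (2 * lengthscale^2))
  cK <- chol(K + diag(1e-10, nrow(U)))
  alpha <- backsolve(cK, backsolve(cK, y - mean(y), transpose = TRUE))
  mu <- mean(y) + as.vector(Ks %*% alpha)
  V <- backsolve(cK, t(Ks), transpose = TRUE)
  s2 <- pmax(sf2 - colSums(V^2), 1e-12)
  list(mean = mu, sd = sqrt(s2))
}

expected_improvement <- function(mu, sd, best) {
  g <- (mu - best) / sd
  sd * (g * stats::pnorm(g) + stats::dnorm(g))
}

#' Bayesian optimization of a scored configuration space
#'
#' Maximizes `objective(hyper)` over a bounded hyperparameter space in
#' `n_iters` evaluations: the declared defaults first, then a mix of random
#' exploration (fraction `exploration`) and expected-improvement proposals
#' from a Gaussian-process surrogate. The incumbent can therefore never score
#' below the evaluated default.
#'
#' @param objective function taking a named hyperparameter list, returning a
#'   scalar score (higher is better).
#' @param space named list of bounded parameters (see the registry).
#' @param n_iters total evaluation budget (>= 1).
#' @param seed integer seed.
#' @param exploration fraction of post-default iterations drawn uniformly.
#' @param n_candidates size of the EI candidate pool.
#' @return list with `best_hyper`, `best_score` and the evaluation `history`
#'   data.frame.
#' @export
bayes_optimize <- function(objective, space, n_iters = 25L, seed = 1L,
                           exploration = 0.2, n_candidates = 256L) {
  stopifnot(length(space) >= 1L, n_iters >= 1L)
  d <- length(space)
  U <- matrix(numeric(0), 0L, d)
  ys <- numeric(0)
  hypers <- list()
  rng <- with_seed(derive_seed(seed, "bo_draws"), {
    list(explore = stats::runif(n_iters),
         points = matrix(stats::runif(n_iters * n_candidates * d),
                         ncol = d))
  })
  offset <- 0L
  for (it in seq_len(n_iters)) {
    if (it == 1L) {
      hyper <- space_defaults(space)
      u <- space_encode(hyper, space)
    } else if (rng$explore[it] < exploration || nrow(U) < 2L) {
      u <- rng$points[offset + 1L, ]
      offset <- offset + 1L
      hyper <- space_decode(u, space)
    } else {
      cand <- rng$points[offset + seq_len(n_candidates), , drop = FALSE]
      offset <- offset + n_candidates
      post <- gp_posterior(U, ys, cand)
      ei <- expected_improvement(post$mean, post$sd, max(ys))
      u <- cand[which.max(ei), ]
      hyper <- space_decode(u, space)
    }
    # re-encode so integer rounding is reflected in the surrogate's inputs
    u <- space_encode(hyper, space)
    sc <- objective(hyper)
    U <- rbind(U, u)
    ys <- c(ys, sc)
    hypers[[it]] <- hyper
  }
  best <- which.max(ys)
  history <- data.frame(iter = seq_len(n_iters), score = ys)
  list(best_hyper = hypers[[best]], best_score = ys[best],
       history = history)
}
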