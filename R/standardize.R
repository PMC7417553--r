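#' Fit a standardizer on training rows only
#'
#' Per-feature mean and sample standard deviation (n - 1 denominator) of the
#' training block. Zero-variance training features get sd fixed at 1 so they
#' are centered but not scaled, keeping column counts stable across CV
#' splits.
#'
#' @param train_block complete numeric matrix (impute first).
#' @return object of class `standardizer_params` with `mean` and `sd`
#'   vectors.
#' @export
fit_standardizer <- function(train_block) {
  stopifnot(is.matrix(train_block))
  if (anyNA(train_block)) stop("standardizer requires a complete block")
  mu <- colMeans(train_block)
  sd <- apply(train_block, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd, features = colnames(train_block)),
            class = "standardizer_params")
}

#' Apply a fitted standardizer
#'
#' Returns `(x - mean) / sd` using the training-derived parameters only; the
#' block being transformed never influences them.
#'
#' @param params a `standardizer_params` from [fit_standardizer()].
#' @param block complete numeric matrix with the same features.
#' @return standardized matrix.
#' @export
apply_standardizer <- function(params, block) {
  stopifnot(inherits(params, "standardizer_params"), is.matrix(block))
  if (!identical(colnames(block), params$features)) {
    stop("block features do not match the fitted standardizer")
  }
  sweep(sweep(block, 2L, params$mean), 2L, params$sd, "/")
}
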