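#' Derive a stage seed from a master seed
#'
#' One master seed deterministically expands to independent per-stage,
#' per-replication seeds; no stage ever consumes global randomness directly.
#' The derivation is a small multiplicative string hash folded with the
#' replication index, kept below 2^31 so the result is a valid R integer.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. "outer_split", "imputer").
#' @param index non-negative integer replication / cell index.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 16807 + as.numeric(index) * 69621 + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Digest of a fitted-parameter object
#'
#' Serializes all numeric content of a (possibly nested) parameter list to a
#' fixed-precision text form and reduces it to a single checksum. Used by the
#' leakage audit: any change to any fitted parameter changes the digest.
#'
#' @param params list, vector or other R object of fitted parameters.
#' @return a single character checksum.
#' @export
param_digest <- function(params) {
  flat <- unlist(params, use.names = TRUE)
  if (is.null(flat)) flat <- ""
  txt <- paste(names(flat), vapply(flat, function(v) {
    if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
  }, character(1)), collapse = "|")
  codes <- utf8ToInt(txt)
  m <- 2147483647
  h1 <- 0; h2 <- 0
  for (i in seq_along(codes)) {
    h1 <- (h1 * 131 + codes[i]) %% m
    h2 <- (h2 * 137 + codes[i] * (i %% 251 + 1)) %% m
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

# round() follows IEC 60559 (banker's rounding); splits use the conventional
# "round half up" so the 75/25 rule is unambiguous across platforms.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
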