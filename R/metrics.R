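#' Balanced accuracy
#'
#' Mean of sensitivity and specificity. Robust to class imbalance: random
#' classification scores 0.5 regardless of the label split, perfect
#' classification scores 1.
#'
#' @param y_true 0/1 vector; both classes must be present.
#' @param y_pred 0/1 vector of the same length.
#' @return score in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(unique(y_true)) < 2L) {
    stop("balanced accuracy requires both classes in y_true")
  }
  sens <- mean(y_pred[y_true == 1] == 1)
  spec <- mean(y_pred[y_true == 0] == 0)
  (sens + spec) / 2
}

#' Normalized mean squared error
#'
#' Mean squared prediction error divided by the *population* variance of the
#' true outcomes on the evaluation split. Under this convention predicting
#' the evaluation mean gives exactly 1 (the chance level); 0 is perfect
#' prediction.
#'
#' @param y_true numeric vector, length >= 2, non-constant.
#' @param y_pred numeric vector of the same length.
#' @return score >= 0.
#' @export
nmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  v <- mean((y_true - mean(y_true))^2)
  if (v == 0) stop("NMSE undefined for constant y_true")
  mean((y_true - y_pred)^2) / v
}

#' Summarize per-replication scores
#'
#' Mean, 95% percentile confidence interval across CV replications, and a
#' significance flag: significant iff the interval excludes the chance level
#' on the favorable side (above chance for scores where higher is better,
#' below for error scores). A constant score vector yields the degenerate
#' interval `[s, s]`.
#'
#' @param scores numeric vector of per-replication scores (>= 2 for a
#'   non-degenerate interval).
#' @param chance_level the score of an uninformative predictor (0.5 for
#'   balanced accuracy, 1 for NMSE).
#' @param better `"higher"` (accuracy-like) or `"lower"` (error-like).
#' @return list with `mean`, `ci` (length 2), `significant`, `n`.
#' @export
summarize_scores <- function(scores, chance_level,
                             better = c("higher", "lower")) {
  better <- match.arg(better)
  stopifnot(is.numeric(scores), length(scores) >= 1L)
  ci <- unname(stats::quantile(scores, c(0.025, 0.975), type = 7))
  significant <- if (better == "higher") {
    ci[1L] > chance_level
  } else {
    ci[2L] < chance_level
  }
  list(mean = mean(scores), ci = ci, significant = significant,
       n = length(scores))
}

#' Paired comparison of two algorithms across CV replications
#'
#' Two-sided paired sign-flip permutation test on the per-replication score
#' differences: under the null that neither algorithm is better, each
#' replication's difference is symmetric around zero, so its sign can be
#' flipped freely. The statistic is the mean difference; identical score
#' vectors give p = 1.
#'
#' @param scores_a,scores_b equal-length numeric vectors, paired by
#'   replication.
#' @param n_perm number of random sign assignments (default 10^4).
#' @param seed integer seed.
#' @return p-value in `(0, 1]`.
#' @export
compare_algorithms <- function(scores_a, scores_b, n_perm = 10000L,
                               seed = 1L) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired comparison requires equal-length score vectors")
  }
  d <- scores_a - scores_b
  obs <- abs(mean(d))
  if (all(d == 0)) return(1)
  n <- length(d)
  with_seed(derive_seed(seed, "signflip"), {
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    perm <- abs(flips %*% d) / n
    (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  })
}
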