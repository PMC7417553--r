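# Inner cross-validation scoring and single-configuration tuning. The inner
# loop never sees outer test rows: it only ever receives the training block
# handed to tune_and_fit().

# Stratified (classification) or plain (regression) fold assignment.
make_folds <- function(y, k, seed, task) {
  n <- length(y)
  with_seed(seed, {
    folds <- integer(n)
    if (task == "classification") {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds[] <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

# Out-of-fold predictions for one configuration + hyperparameter setting.
# Returns the pooled OOF prediction vector (scores or values) in row order.
oof_predictions <- function(config, hyper, X, y, folds, seed) {
  k <- max(folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (config$task == "classification" && length(unique(y[tr])) < 2L) {
      # degenerate fold: fall back to the training-class constant
      oof[!tr] <- mean(y[tr])
      next
    }
    m <- fit_engine(config, hyper, X[tr, , drop = FALSE], y[tr],
                    seed = derive_seed(seed, "inner_fit", f))
    oof[!tr] <- predict_engine(m, X[!tr, , drop = FALSE])
  }
  oof
}

# Inner-CV score of a hyperparameter setting: BACC of the pooled OOF hard
# labels for classification, negative NMSE for regression.
inner_cv_score <- function(config, hyper, X, y, folds, seed) {
  oof <- oof_predictions(config, hyper, X, y, folds, seed)
  score_predictions(y, oof, config$task)
}

score_predictions <- function(y, pred, task) {
  if (task == "classification") {
    if (length(unique(y)) < 2L) return(NA_real_)
    balanced_accuracy(y, as.numeric(pred >= 0.5))
  } else {
    -nmse(y, pred)
  }
}

#' Tune (if requested) and fit one registry configuration
#'
#' Defaults-mode configurations are fitted directly with their declared
#' settings; `bayes_opt` configurations first run Bayesian optimization of
#' the inner-CV score (balanced accuracy, or negative NMSE for regression)
#' over their bounded search space, evaluating the declared default as the
#' first point, then refit on the full training data at the incumbent. The
#' inner loop uses stratified 3-fold CV by default. Deterministic given
#' `seed`.
#'
#' @param config an `algorithm_config` from the registry.
#' @param X complete numeric training matrix (impute and standardize first).
#' @param y numeric outcome: 0/1 labels (classification) or real responses.
#' @param inner_folds number of inner CV folds (>= 2; default 3).
#' @param n_opt_iters Bayesian-optimization evaluation budget (default 25).
#' @param seed integer seed.
#' @return object of class `fitted_model` carrying the chosen
#'   hyperparameters, the engine fit, the inner-CV score of the chosen
#'   setting and its out-of-fold predictions.
#' @export
tune_and_fit <- function(config, X, y, inner_folds = 3L, n_opt_iters = 25L,
                         seed = 1L) {
  stopifnot(inherits(config, "algorithm_config"), is.matrix(X),
            nrow(X) == length(y), inner_folds >= 2L)
  if (anyNA(X)) stop("training matrix contains missing values; impute first")
  if (nrow(X) < inner_folds) stop("fewer training rows than inner folds")
  if (config$task == "classification" && length(unique(y)) < 2L) {
    stop("training outcome has a single class")
  }
  folds <- make_folds(y, inner_folds, derive_seed(seed, "inner_folds"),
                      config$task)
  if (config$mode == "bayes_opt") {
    objective <- function(hyper) {
      inner_cv_score(config, c(config$fixed, hyper), X, y, folds,
                     seed = derive_seed(seed, "inner_eval"))
    }
    bo <- bayes_optimize(objective, config$search_space,
                         n_iters = n_opt_iters,
                         seed = derive_seed(seed, "bo"))
    hyper <- c(config$fixed, bo$best_hyper)
    inner_score <- bo$best_score
  } else {
    hyper <- config$fixed
    inner_score <- inner_cv_score(config, hyper, X, y, folds,
                                  seed = derive_seed(seed, "inner_eval"))
  }
  oof <- oof_predictions(config, hyper, X, y, folds,
                         seed = derive_seed(seed, "inner_eval"))
  engine <- fit_engine(config, hyper, X, y,
                       seed = derive_seed(seed, "final_fit"))
  structure(
    list(config_id = config$id, family = config$family, task = config$task,
         hyper = hyper, inner_score = inner_score, engine = engine,
         oof = oof, folds = folds),
    class = "fitted_model"
  )
}

#' Predict from a fitted model
#'
#' Classification models return per-subject class-1 scores in `[0, 1]`
#' (hard labels via [hard_labels()], threshold 0.5, ties to class 1);
#' regression models return real values.
#'
#' @param object a `fitted_model`.
#' @param newdata numeric matrix, column-compatible with training.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  predict_engine(object$engine, newdata)
}

#' Hard class labels from scores
#'
#' Threshold 0.5; a score of exactly 0.5 is assigned class 1.
#'
#' @param score numeric vector of class-1 scores in `[0, 1]`.
#' @return numeric 0/1 labels.
#' @export
hard_labels <- function(score) as.numeric(score >= 0.5)

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model:", x$config_id, "(", x$family, ",", x$task, ")\n")
  cat("  inner-CV score:", sprintf("%.4f", x$inner_score), "\n")
  hp <- x$hyper
  if (length(hp)) {
    cat("  hyperparameters:",
        paste(names(hp), vapply(hp, function(v) format(v, digits = 4),
                                character(1)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
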