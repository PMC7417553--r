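#' Specify an auto-ensemble search
#'
#' The two knobs whose impact the framework grids over: the search budget
#' (how long to look for candidate algorithm configurations) and the maximum
#' number of members in the final ensemble. The canonical grid crosses
#' budgets of 20, 60 and 180 with maximum ensemble sizes of 1, 4 and 40. By
#' default the budget counts candidate evaluations, which is
#' hardware-independent and exactly reproducible; `budget_type = "seconds"`
#' gives the wall-clock reading instead.
#'
#' @param budget positive number: candidate evaluations (default
#'   interpretation) or seconds.
#' @param max_ensemble_size positive integer cap on ensemble members.
#' @param seed integer seed.
#' @param budget_type `"evaluations"` or `"seconds"`.
#' @return object of class `ensemble_search_spec`.
#' @export
ensemble_search_spec <- function(budget = 60, max_ensemble_size = 4L,
                                 seed = 1L,
                                 budget_type = c("evaluations", "seconds")) {
  budget_type <- match.arg(budget_type)
  stopifnot(budget > 0, max_ensemble_size >= 1L)
  structure(
    list(budget = budget, max_ensemble_size = as.integer(max_ensemble_size),
         seed = as.integer(seed), budget_type = budget_type),
    class = "ensemble_search_spec"
  )
}

#' Budgeted automatic ensemble construction
#'
#' Samples candidate configurations from the registry until the budget is
#' exhausted — hyperparameters of searchable configurations are proposed by
#' the same expected-improvement machinery as [tune_and_fit()], warm-started
#' per configuration — then builds the final model by greedy forward
#' selection *with replacement* on the held-out inner-CV predictions
#' (ensemble selection). Selection stops at `max_ensemble_size` picks and the
#' returned ensemble is the best-scoring prefix, so its inner-CV score is
#' never below that of its best single member. Member weights are selection
#' frequencies.
#'
#' @param X complete numeric training matrix.
#' @param y numeric outcome (0/1 labels or real responses).
#' @param spec an [ensemble_search_spec()].
#' @param inner_folds inner CV folds (default 3).
#' @param task `"classification"` or `"regression"`.
#' @param reg registry to draw candidates from; defaults to the task's
#'   registry.
#' @return object of class `ensemble_model`.
#' @export
auto_ensemble_fit <- function(X, y, spec, inner_folds = 3L,
                              task = c("classification", "regression"),
                              reg = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "ensemble_search_spec"), is.matrix(X))
  if (anyNA(X)) stop("training matrix contains missing values; impute first")
  if (is.null(reg)) reg <- registry(task)
  folds <- make_folds(y, inner_folds,
                      derive_seed(spec$seed, "ens_folds"), task)

  draw <- with_seed(derive_seed(spec$seed, "ens_draw"), {
    n_max <- if (spec$budget_type == "evaluations") {
      as.integer(spec$budget)
    } else {
      10000L # wall-clock mode: loop until time is up
    }
    list(cfg = sample.int(length(reg), n_max, replace = TRUE),
         explore = stats::runif(n_max),
         unif = matrix(stats::runif(n_max * 16L), nrow = n_max))
  })

  candidates <- list()
  bo_history <- list() # per config id: encoded points + scores
  t0 <- proc.time()[["elapsed"]]
  i <- 0L
  repeat {
    i <- i + 1L
    if (spec$budget_type == "evaluations") {
      if (i > spec$budget) break
    } else {
      if (i > 1L && proc.time()[["elapsed"]] - t0 > spec$budget) break
      if (i > length(draw$cfg)) break
    }
    config <- reg[[draw$cfg[i]]]
    space <- config$search_space
    if (length(space) == 0L) {
      hyper <- config$fixed
    } else {
      hist <- bo_history[[config$id]]
      d <- length(space)
      u <- if (is.null(hist) || nrow(hist$U) < 2L ||
               draw$explore[i] < 0.2) {
        if (is.null(hist)) {
          space_encode(space_defaults(space), space) # default first
        } else {
          draw$unif[i, seq_len(d)]
        }
      } else {
        cand <- matrix(with_seed(derive_seed(spec$seed, "ens_cand", i),
                                 stats::runif(128L * d)), ncol = d)
        post <- gp_posterior(hist$U, hist$y, cand)
        ei <- expected_improvement(post$mean, post$sd, max(hist$y))
        cand[which.max(ei), ]
      }
      hyper <- c(config$fixed, space_decode(u, space))
    }
    oof <- oof_predictions(config, hyper, X, y, folds,
                           seed = derive_seed(spec$seed, "ens_eval", i))
    sc <- score_predictions(y, oof, task)
    candidates[[i]] <- list(config = config, hyper = hyper, oof = oof,
                            score = sc)
    if (length(space) > 0L) {
      u_eval <- space_encode(hyper[names(space)], space)
      hist <- bo_history[[config$id]] %||% list(U = matrix(numeric(0), 0L,
                                                           length(space)),
                                                y = numeric(0))
      bo_history[[config$id]] <- list(U = rbind(hist$U, u_eval),
                                      y = c(hist$y, sc))
    }
  }
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0L) stop("budget too small to evaluate any candidate")

  # greedy forward selection with replacement on held-out predictions;
  # keep the best-scoring prefix of the selection path
  sel <- integer(0)
  sum_oof <- rep(0, length(y))
  best_sel <- integer(0)
  best_score <- -Inf
  for (step in seq_len(spec$max_ensemble_size)) {
    scores <- vapply(candidates, function(cand) {
      score_predictions(y, (sum_oof + cand$oof) / (step), task)
    }, numeric(1))
    pick <- which.max(scores)
    sel <- c(sel, pick)
    sum_oof <- sum_oof + candidates[[pick]]$oof
    if (scores[pick] > best_score) {
      best_score <- scores[pick]
      best_sel <- sel
    }
  }

  counts <- table(best_sel)
  members <- lapply(seq_along(counts), function(j) {
    idx <- as.integer(names(counts)[j])
    cand <- candidates[[idx]]
    engine <- fit_engine(cand$config, cand$hyper, X, y,
                         seed = derive_seed(spec$seed, "ens_final", idx))
    list(config_id = cand$config$id, hyper = cand$hyper, engine = engine,
         weight = as.numeric(counts[j]) / length(best_sel))
  })
  structure(
    list(members = members, task = task, inner_score = best_score,
         n_candidates = length(candidates), spec = spec,
         selection = best_sel),
    class = "ensemble_model"
  )
}

#' Predict from an auto-ensemble
#'
#' The ensemble prediction is the weighted mean of member predictions
#' (class-1 scores for classification, values for regression).
#'
#' @param object an `ensemble_model`.
#' @param newdata numeric matrix, column-compatible with training.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  preds <- vapply(object$members,
                  function(m) predict_engine(m$engine, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  w <- vapply(object$members, `[[`, numeric(1), "weight")
  as.numeric(preds %*% w)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model:", length(x$members), "member(s) from",
      x$n_candidates, "candidate evaluations\n")
  for (m in x$members) {
    cat(sprintf("  %-20s weight %.2f\n", m$config_id, m$weight))
  }
  cat("  inner-CV score:", sprintf("%.4f", x$inner_score), "\n")
  invisible(x)
}
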