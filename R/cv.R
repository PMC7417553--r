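#' Specify the outer cross-validation loop
#'
#' Random 75/25 train/test splits (test size = round(n x test_fraction),
#' remainder to training), replicated `n_replications` times, stratified by
#' outcome or by cohort. Ten replications are the simulation default; 100
#' the real-data scale.
#'
#' @param test_fraction fraction of subjects left out for testing (default
#'   0.25).
#' @param n_replications number of outer splits (default 10).
#' @param stratify_by `"outcome"` or `"cohort"`.
#' @param seed integer seed; all splits derive from it.
#' @return object of class `outer_cv_spec`.
#' @export
outer_cv_spec <- function(test_fraction = 0.25, n_replications = 10L,
                          stratify_by = c("outcome", "cohort"), seed = 1L) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(test_fraction > 0, test_fraction < 1, n_replications >= 1L)
  structure(
    list(test_fraction = test_fraction,
         n_replications = as.integer(n_replications),
         stratify_by = stratify_by, seed = as.integer(seed)),
    class = "outer_cv_spec"
  )
}

# Stratified split: test counts per stratum by largest remainder, so the
# total equals round(n * test_fraction) and each stratum's test share is
# within one subject of its overall share.
stratified_split <- function(strata, test_fraction, seed) {
  n <- length(strata)
  test_n <- round_half_up(n * test_fraction)
  with_seed(seed, {
    levels <- unique(strata)
    quota <- test_n * (table(factor(strata, levels = levels)) / n)
    base <- floor(quota)
    rem <- quota - base
    short <- test_n - sum(base)
    if (short > 0) {
      bump <- order(rem, decreasing = TRUE)[seq_len(short)]
      base[bump] <- base[bump] + 1
    }
    test_idx <- integer(0)
    for (li in seq_along(levels)) {
      idx <- which(strata == levels[li])
      k <- min(base[li], length(idx))
      if (k > 0) test_idx <- c(test_idx, sample(idx, k))
    }
    sort(test_idx)
  })
}

# Fit the full per-submodality pipeline on training rows and predict the
# test rows. Returns predictions, the submodality's inner-CV score and
# (optionally) fitted-parameter digests for the leakage audit.
fit_submodality <- function(sub, train_idx, test_idx, y, model, task,
                            imputation, inner_folds, n_opt_iters, seed,
                            collect_digests = FALSE) {
  rows_tr <- train_idx[!sub$block_missing[train_idx]]
  rows_te <- test_idx[!sub$block_missing[test_idx]]
  pred <- rep(NA_real_, length(test_idx))
  empty <- list(pred = pred, inner_score = NA_real_, digests = NULL,
                used = FALSE)
  if (length(rows_tr) < max(2L * inner_folds, 8L)) return(empty)
  if (task == "classification" && length(unique(y[rows_tr])) < 2L) {
    return(empty)
  }
  block <- sub$block
  # features with no observed training value cannot be imputed; drop them
  # for this replication (covariate columns are always complete)
  keep <- colSums(!is.na(block[rows_tr, , drop = FALSE])) > 0L
  block <- block[, keep, drop = FALSE]

  imp <- fit_imputer(block[rows_tr, , drop = FALSE], method = imputation,
                     seed = derive_seed(seed, "imputer"))
  Xtr <- apply_imputer(imp, block[rows_tr, , drop = FALSE])
  std <- fit_standardizer(Xtr)
  Xtr <- apply_standardizer(std, Xtr)

  if (inherits(model, "ensemble_search_spec")) {
    m <- model
    m$seed <- derive_seed(seed, "ens")
    fitted <- auto_ensemble_fit(Xtr, y[rows_tr], m,
                                inner_folds = inner_folds, task = task)
    hyper_info <- lapply(fitted$members, function(mm)
      list(id = mm$config_id, hyper = mm$hyper, weight = mm$weight))
  } else {
    fitted <- tune_and_fit(model, Xtr, y[rows_tr],
                           inner_folds = inner_folds,
                           n_opt_iters = n_opt_iters,
                           seed = derive_seed(seed, "tune"))
    hyper_info <- fitted$hyper
  }

  if (length(rows_te) > 0L) {
    Xte <- apply_imputer(imp, block[rows_te, , drop = FALSE])
    Xte <- apply_standardizer(std, Xte)
    pred[match(rows_te, test_idx)] <- stats::predict(fitted, Xte)
  }
  digests <- NULL
  if (collect_digests) {
    digests <- list(
      imputer = param_digest(imp[setdiff(names(imp), "loglik_trace")]),
      standardizer = param_digest(std),
      model = param_digest(hyper_info)
    )
  }
  list(pred = pred, inner_score = fitted$inner_score, digests = digests,
       used = TRUE)
}

#' Late integration of per-submodality predictions
#'
#' Combines the available submodality predictions of each subject into one
#' prediction: the unweighted mean (`"mean"` scheme) or a weighted mean with
#' weights proportional to each submodality's inner-CV score, renormalized
#' over the submodalities available for that subject (`"weighted"` scheme).
#' Block-wise missingness therefore reduces a subject's integration to the
#' blocks they actually have.
#'
#' @param preds numeric matrix, subjects x submodalities; `NA` where a
#'   submodality has no prediction for a subject.
#' @param scheme `"mean"` or `"weighted"`.
#' @param weights per-submodality weights (weighted scheme); non-positive or
#'   missing weights drop to a small floor so every available block retains
#'   a voice.
#' @param fallback optional constant used for subjects with no available
#'   submodality; without it such a subject is an error.
#' @return numeric vector of integrated predictions (class-1 scores or
#'   regression values).
#' @export
late_integrate <- function(preds, scheme = c("mean", "weighted"),
                           weights = NULL, fallback = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(preds))
  w <- if (scheme == "mean" || is.null(weights)) {
    rep(1, ncol(preds))
  } else {
    pmax(as.numeric(weights), 1e-6)
  }
  w[is.na(w)] <- 1e-6
  out <- vapply(seq_len(nrow(preds)), function(i) {
    avail <- !is.na(preds[i, ])
    if (!any(avail)) {
      if (is.null(fallback)) {
        stop("subject ", i, " has no available submodality prediction")
      }
      return(fallback)
    }
    sum(preds[i, avail] * w[avail]) / sum(w[avail])
  }, numeric(1))
  out
}

# Submodality weight for the weighted integration scheme: inner-CV balanced
# accuracy for classification; the skill score max(1 - NMSE, 0) for
# regression (inner scores are stored as negative NMSE).
integration_weights <- function(inner_scores, task) {
  if (task == "classification") inner_scores
  else pmax(1 + inner_scores, 0)
}

#' Outer cross-validation of one modelling approach on one dataset
#'
#' The leakage-proof evaluation loop: per replication, a stratified 75/25
#' split; per submodality, imputer and standardizer fitted on training rows
#' only, the model tuned in the inner 3-fold CV loop (single-configuration
#' or budgeted auto-ensemble), test predictions combined across
#' submodalities by late integration, and the replication scored by balanced
#' accuracy (classification) or NMSE (regression). Replications whose
#' training split degenerates to a single class are redrawn with a logged
#' sub-seed.
#'
#' @param dataset a [multimodal_dataset()].
#' @param model an `algorithm_config` (single-algorithm approach) or an
#'   [ensemble_search_spec()] (auto-ensemble approach).
#' @param task `"classification"` (uses `outcomes$label`) or `"regression"`
#'   (uses `outcomes$response`).
#' @param cv an [outer_cv_spec()].
#' @param integration late-integration scheme, `"mean"` or `"weighted"`.
#' @param imputation `"median"` or `"ppca"`.
#' @param inner_folds inner CV folds (default 3).
#' @param n_opt_iters Bayesian-optimization budget per submodality model.
#' @param collect_digests record fitted-parameter digests per replication
#'   and submodality (the leakage audit trail).
#' @return object of class `cv_result`: per-replication scores, predictions
#'   and test ids, plus the aggregate mean, 95% percentile CI and
#'   significance versus chance.
#' @export
outer_cv <- function(dataset, model, task = c("classification", "regression"),
                     cv = outer_cv_spec(),
                     integration = c("mean", "weighted"),
                     imputation = c("median", "ppca"),
                     inner_folds = 3L, n_opt_iters = 25L,
                     collect_digests = FALSE) {
  task <- match.arg(task)
  integration <- match.arg(integration)
  imputation <- match.arg(imputation)
  stopifnot(inherits(dataset, "multimodal_dataset"),
            inherits(cv, "outer_cv_spec"))

  y_all <- if (task == "classification") {
    dataset$outcomes$label
  } else {
    dataset$outcomes$response
  }
  usable <- which(!is.na(y_all))
  if (length(usable) < 12L) stop("too few subjects with outcomes for CV")
  y <- y_all[usable]
  if (task == "classification" && length(unique(y)) < 2L) {
    stop("classification requires both classes among the outcomes")
  }
  strata <- if (cv$stratify_by == "outcome") {
    if (task == "classification") as.character(y) else rep("all", length(y))
  } else {
    as.character(dataset$covariates$cohort[usable])
  }
  subs <- split_into_submodalities(dataset)
  # restrict blocks to usable subjects once
  for (s in seq_along(subs)) {
    subs[[s]]$block <- subs[[s]]$block[usable, , drop = FALSE]
    subs[[s]]$block_missing <- subs[[s]]$block_missing[usable]
  }
  ids <- dataset$subject_ids[usable]

  replications <- vector("list", cv$n_replications)
  scores <- numeric(cv$n_replications)
  for (r in seq_len(cv$n_replications)) {
    attempt <- 0L
    repeat {
      split_seed <- derive_seed(cv$seed, "outer_split",
                                r * 1000L + attempt)
      test_idx <- stratified_split(strata, cv$test_fraction, split_seed)
      train_idx <- setdiff(seq_along(y), test_idx)
      ok <- TRUE
      if (task == "classification") {
        ok <- length(unique(y[train_idx])) == 2L &&
          length(unique(y[test_idx])) == 2L
      } else {
        ok <- stats::var(y[test_idx]) > 0
      }
      if (ok || attempt >= 50L) break
      attempt <- attempt + 1L
    }
    rep_seed <- derive_seed(cv$seed, "replication", r)

    fits <- lapply(seq_along(subs), function(s) {
      fit_submodality(subs[[s]], train_idx, test_idx, y, model, task,
                      imputation, inner_folds, n_opt_iters,
                      seed = derive_seed(rep_seed, names(subs)[s]),
                      collect_digests = collect_digests)
    })
    names(fits) <- names(subs)
    pred_mat <- vapply(fits, `[[`, numeric(length(test_idx)), "pred")
    pred_mat <- matrix(pred_mat, nrow = length(test_idx),
                       dimnames = list(ids[test_idx], names(subs)))
    inner_scores <- vapply(fits, `[[`, numeric(1), "inner_score")
    fallback <- if (task == "classification") {
      mean(y[train_idx]) # training class-1 rate as a neutral score
    } else {
      mean(y[train_idx])
    }
    integrated <- late_integrate(
      pred_mat, scheme = integration,
      weights = integration_weights(inner_scores, task),
      fallback = fallback)
    scores[r] <- if (task == "classification") {
      balanced_accuracy(y[test_idx], hard_labels(integrated))
    } else {
      nmse(y[test_idx], integrated)
    }
    replications[[r]] <- list(
      test_ids = ids[test_idx], integrated = integrated,
      submodality_predictions = pred_mat,
      inner_scores = inner_scores, score = scores[r],
      resplit_attempts = attempt,
      digests = if (collect_digests) lapply(fits, `[[`, "digests") else NULL
    )
  }
  chance <- if (task == "classification") 0.5 else 1
  better <- if (task == "classification") "higher" else "lower"
  structure(
    list(task = task,
         model_id = if (inherits(model, "algorithm_config")) model$id
                    else "auto_ensemble",
         scores = scores,
         summary = summarize_scores(scores, chance, better),
         chance_level = chance, better = better,
         replications = replications, cv = cv,
         integration = integration, imputation = imputation),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  metric <- if (x$task == "classification") "BACC" else "NMSE"
  cat(sprintf("cv_result: %s, %s over %d replications\n",
              x$model_id, metric, s$n))
  cat(sprintf("  mean %.3f, 95%% CI [%.3f, %.3f]%s\n", s$mean,
              s$ci[1], s$ci[2],
              if (s$significant) " (significant vs chance)" else ""))
  invisible(x)
}
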