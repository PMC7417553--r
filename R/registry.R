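# The learner-configuration registries are versioned constants: 21
# classification configurations drawn from 8 algorithm families and 32
# regression configurations from 9 families, mixing fixed-default and
# Bayesian-optimization modes (plus kernel variants for SVMs). Counts and
# family coverage are frozen and guarded by tests; the per-family
# hyperparameter inventories are this package's own.

param <- function(lower, upper, default, type = "double", log = FALSE) {
  list(lower = lower, upper = upper, default = default, type = type,
       log = log)
}

algorithm_config <- function(id, task, family, engine, mode = "defaults",
                             fixed = list(), search_space = list()) {
  stopifnot(mode %in% c("defaults", "bayes_opt"))
  if (mode == "bayes_opt" && length(search_space) == 0L) {
    stop("bayes_opt config '", id, "' needs a non-empty search space")
  }
  for (pn in names(search_space)) {
    sp <- search_space[[pn]]
    if (!is.finite(sp$lower) || !is.finite(sp$upper) || sp$lower >= sp$upper) {
      stop("unbounded or empty range for parameter '", pn, "' of '", id, "'")
    }
  }
  structure(list(id = id, task = task, family = family, engine = engine,
                 mode = mode, fixed = fixed, search_space = search_space),
            class = "algorithm_config")
}

#' The classification configuration registry
#'
#' Exactly 21 configurations from exactly 8 algorithm families: logistic
#' regression, naive Bayes, random forest, decision tree, tree ensemble
#' (gradient boosting), support-vector machines (linear / polynomial /
#' radial kernels), k-nearest neighbour, and a regularized high-dimensional
#' linear classifier. Configurations are either fixed defaults or carry a
#' bounded search space optimized by [tune_and_fit()] in the inner CV loop.
#'
#' @return named list of `algorithm_config` objects, length 21.
#' @export
classification_registry <- function() {
  cfgs <- list(
    algorithm_config("logreg_default", "classification",
                     "logistic_regression", "logistic"),

    algorithm_config("nb_default", "classification", "naive_bayes",
                     "naive_bayes"),

    algorithm_config("rf_default", "classification", "random_forest",
                     "random_forest", fixed = list(ntree = 200)),
    algorithm_config("rf_500", "classification", "random_forest",
                     "random_forest", fixed = list(ntree = 500)),
    algorithm_config("rf_bo", "classification", "random_forest",
                     "random_forest", mode = "bayes_opt",
                     fixed = list(ntree = 200),
                     search_space = list(
                       mtry_frac = param(0.1, 0.9, 0.33),
                       nodesize = param(1, 10, 1, type = "integer"))),

    algorithm_config("cart_default", "classification", "decision_tree",
                     "rpart"),
    algorithm_config("cart_bo", "classification", "decision_tree", "rpart",
                     mode = "bayes_opt",
                     search_space = list(
                       cp = param(1e-4, 0.5, 0.01, log = TRUE),
                       minsplit = param(2, 40, 20, type = "integer"))),

    algorithm_config("xgb_default", "classification", "tree_ensemble",
                     "xgboost",
                     fixed = list(eta = 0.3, max_depth = 6, nrounds = 50)),
    algorithm_config("xgb_shallow", "classification", "tree_ensemble",
                     "xgboost",
                     fixed = list(eta = 0.1, max_depth = 2, nrounds = 100)),
    algorithm_config("xgb_bo", "classification", "tree_ensemble", "xgboost",
                     mode = "bayes_opt",
                     search_space = list(
                       eta = param(0.01, 0.5, 0.3, log = TRUE),
                       max_depth = param(2, 8, 6, type = "integer"),
                       nrounds = param(20, 200, 50, type = "integer"))),

    algorithm_config("svm_linear_default", "classification", "svm", "svm",
                     fixed = list(kernel = "linear", cost = 1)),
    algorithm_config("svm_linear_bo", "classification", "svm", "svm",
                     mode = "bayes_opt", fixed = list(kernel = "linear"),
                     search_space = list(
                       cost = param(1e-3, 1e3, 1, log = TRUE))),
    algorithm_config("svm_poly_default", "classification", "svm", "svm",
                     fixed = list(kernel = "polynomial", cost = 1,
                                  degree = 3)),
    algorithm_config("svm_poly_bo", "classification", "svm", "svm",
                     mode = "bayes_opt", fixed = list(kernel = "polynomial"),
                     search_space = list(
                       cost = param(1e-3, 1e3, 1, log = TRUE),
                       degree = param(2, 4, 3, type = "integer"))),
    algorithm_config("svm_rbf_default", "classification", "svm", "svm",
                     fixed = list(kernel = "radial", cost = 1)),
    algorithm_config("svm_rbf_bo", "classification", "svm", "svm",
                     mode = "bayes_opt", fixed = list(kernel = "radial"),
                     search_space = list(
                       cost = param(1e-3, 1e3, 1, log = TRUE),
                       gamma = param(1e-4, 10, 0.1, log = TRUE))),

    algorithm_config("knn_default", "classification", "knn", "knn",
                     fixed = list(k = 5)),
    algorithm_config("knn_bo", "classification", "knn", "knn",
                     mode = "bayes_opt",
                     search_space = list(
                       k = param(1, 25, 5, type = "integer"))),

    algorithm_config("hdlin_lasso", "classification",
                     "highdim_linear", "glmnet_class",
                     fixed = list(alpha = 1)),
    algorithm_config("hdlin_ridge", "classification",
                     "highdim_linear", "glmnet_class",
                     fixed = list(alpha = 0)),
    algorithm_config("hdlin_bo", "classification",
                     "highdim_linear", "glmnet_class", mode = "bayes_opt",
                     search_space = list(
                       alpha = param(0, 1, 0.5),
                       lambda = param(1e-4, 10, 0.1, log = TRUE)))
  )
  names(cfgs) <- vapply(cfgs, `[[`, character(1), "id")
  cfgs
}

#' The regression configuration registry
#'
#' Exactly 32 configurations from exactly 9 algorithm families: linear
#' regression, support-vector regression (linear / polynomial / radial
#' kernels), Gaussian processes, regression trees, generalized linear models
#' (elastic net / ridge), boosted ensemble regression, random forest,
#' L1-regularized linear regression (lasso), and an L1-regularized SVM
#' (lasso feature selection followed by a linear epsilon-SVM).
#'
#' @return named list of `algorithm_config` objects, length 32.
#' @export
regression_registry <- function() {
  cfgs <- list(
    algorithm_config("lin_default", "regression", "linear_regression", "lm"),

    algorithm_config("svr_linear_default", "regression", "svm", "svm_reg",
                     fixed = list(kernel = "linear", cost = 1)),
    algorithm_config("svr_linear_bo", "regression", "svm", "svm_reg",
                     mode = "bayes_opt", fixed = list(kernel = "linear"),
                     search_space = list(
                       cost = param(1e-3, 1e3, 1, log = TRUE),
                       epsilon = param(0.01, 1, 0.1, log = TRUE))),
    algorithm_config("svr_poly_default", "regression", "svm", "svm_reg",
                     fixed = list(kernel = "polynomial", cost = 1,
                                  degree = 3)),
    algorithm_config("svr_poly_bo", "regression", "svm", "svm_reg",
                     mode = "bayes_opt", fixed = list(kernel = "polynomial"),
                     search_space = list(
                       cost = param(1e-3, 1e3, 1, log = TRUE),
                       degree = param(2, 4, 3, type = "integer"))),
    algorithm_config("svr_rbf_default", "regression", "svm", "svm_reg",
                     fixed = list(kernel = "radial", cost = 1)),
    algorithm_config("svr_rbf_bo", "regression", "svm", "svm_reg",
                     mode = "bayes_opt", fixed = list(kernel = "radial"),
                     search_space = list(
                       cost = param(1e-3, 1e3, 1, log = TRUE),
                       gamma = param(1e-4, 10, 0.1, log = TRUE))),

    algorithm_config("gp_rbf_default", "regression", "gaussian_process",
                     "gausspr", fixed = list(kernel = "rbfdot")),
    algorithm_config("gp_rbf_bo", "regression", "gaussian_process",
                     "gausspr", mode = "bayes_opt",
                     fixed = list(kernel = "rbfdot"),
                     search_space = list(
                       sigma = param(1e-3, 10, 0.1, log = TRUE))),
    algorithm_config("gp_laplace_default", "regression", "gaussian_process",
                     "gausspr", fixed = list(kernel = "laplacedot")),
    algorithm_config("gp_laplace_bo", "regression", "gaussian_process",
                     "gausspr", mode = "bayes_opt",
                     fixed = list(kernel = "laplacedot"),
                     search_space = list(
                       sigma = param(1e-3, 10, 0.1, log = TRUE))),

    algorithm_config("cart_reg_default", "regression", "regression_tree",
                     "rpart_reg"),
    algorithm_config("cart_reg_pruned", "regression", "regression_tree",
                     "rpart_reg", fixed = list(cp = 0.05)),
    algorithm_config("cart_reg_bo", "regression", "regression_tree",
                     "rpart_reg", mode = "bayes_opt",
                     search_space = list(
                       cp = param(1e-4, 0.5, 0.01, log = TRUE),
                       minsplit = param(2, 40, 20, type = "integer"))),

    algorithm_config("en_default", "regression", "glm", "glmnet_reg",
                     fixed = list(alpha = 0.5)),
    algorithm_config("en_bo", "regression", "glm", "glmnet_reg",
                     mode = "bayes_opt",
                     search_space = list(
                       alpha = param(0, 1, 0.5),
                       lambda = param(1e-4, 10, 0.1, log = TRUE))),
    algorithm_config("ridge_default", "regression", "glm", "glmnet_reg",
                     fixed = list(alpha = 0)),
    algorithm_config("ridge_bo", "regression", "glm", "glmnet_reg",
                     mode = "bayes_opt", fixed = list(alpha = 0),
                     search_space = list(
                       lambda = param(1e-4, 10, 0.1, log = TRUE))),

    algorithm_config("xgbr_default", "regression", "ensemble_regression",
                     "xgboost_reg",
                     fixed = list(eta = 0.3, max_depth = 6, nrounds = 50)),
    algorithm_config("xgbr_slow", "regression", "ensemble_regression",
                     "xgboost_reg",
                     fixed = list(eta = 0.05, max_depth = 3, nrounds = 200)),
    algorithm_config("xgbr_shallow", "regression", "ensemble_regression",
                     "xgboost_reg",
                     fixed = list(eta = 0.1, max_depth = 2, nrounds = 100)),
    algorithm_config("xgbr_bo", "regression", "ensemble_regression",
                     "xgboost_reg", mode = "bayes_opt",
                     search_space = list(
                       eta = param(0.01, 0.5, 0.3, log = TRUE),
                       max_depth = param(2, 8, 6, type = "integer"),
                       nrounds = param(20, 200, 50, type = "integer"))),

    algorithm_config("rfr_default", "regression", "random_forest",
                     "random_forest_reg", fixed = list(ntree = 200)),
    algorithm_config("rfr_500", "regression", "random_forest",
                     "random_forest_reg", fixed = list(ntree = 500)),
    algorithm_config("rfr_node5", "regression", "random_forest",
                     "random_forest_reg",
                     fixed = list(ntree = 200, nodesize = 5)),
    algorithm_config("rfr_bo", "regression", "random_forest",
                     "random_forest_reg", mode = "bayes_opt",
                     fixed = list(ntree = 200),
                     search_space = list(
                       mtry_frac = param(0.1, 0.9, 0.33),
                       nodesize = param(1, 10, 5, type = "integer"))),

    algorithm_config("lasso_default", "regression", "l1_linear",
                     "glmnet_reg", fixed = list(alpha = 1)),
    algorithm_config("lasso_1se", "regression", "l1_linear", "glmnet_reg",
                     fixed = list(alpha = 1, lambda_rule = "lambda.1se")),
    algorithm_config("lasso_bo", "regression", "l1_linear", "glmnet_reg",
                     mode = "bayes_opt", fixed = list(alpha = 1),
                     search_space = list(
                       lambda = param(1e-4, 10, 0.1, log = TRUE))),

    algorithm_config("l1svm_default", "regression", "l1_svm", "l1_svm_reg",
                     fixed = list(cost = 1)),
    algorithm_config("l1svm_tight", "regression", "l1_svm", "l1_svm_reg",
                     fixed = list(cost = 1, lambda_rule = "lambda.1se")),
    algorithm_config("l1svm_bo", "regression", "l1_svm", "l1_svm_reg",
                     mode = "bayes_opt",
                     search_space = list(
                       lambda = param(1e-4, 10, 0.1, log = TRUE),
                       cost = param(1e-3, 1e3, 1, log = TRUE)))
  )
  names(cfgs) <- vapply(cfgs, `[[`, character(1), "id")
  cfgs
}

#' Retrieve a registry by task
#' @param task `"classification"` or `"regression"`.
#' @return named list of `algorithm_config`.
#' @export
registry <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") classification_registry()
  else regression_registry()
}

#' Registry overview table
#' @param task `"classification"` or `"regression"`.
#' @return data.frame with id, family, mode and tuned parameter names.
#' @export
registry_table <- function(task = c("classification", "regression")) {
  reg <- registry(task)
  data.frame(
    id = vapply(reg, `[[`, character(1), "id"),
    family = vapply(reg, `[[`, character(1), "family"),
    mode = vapply(reg, `[[`, character(1), "mode"),
    tuned = vapply(reg, function(cf)
      paste(names(cf$search_space), collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
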