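# Model engines: thin, uniform wrappers around the fitting backends.
# fit_engine() returns an engine object; predict_engine() returns class-1
# scores in [0, 1] for classification engines and real values for regression
# engines. Every engine is deterministic given the seed it is handed.

fit_engine <- function(config, hyper, X, y, seed = 1L) {
  eng <- config$engine
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X), unique = TRUE)
  fit <- with_seed(seed, switch(
    eng,
    logistic = {
      d <- df; d$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = d,
                                  family = stats::binomial()))
    },
    naive_bayes = e1071::naiveBayes(x = df, y = factor(y, levels = c(0, 1))),
    random_forest = {
      mtry <- if (!is.null(hyper$mtry_frac)) {
        max(1L, floor(hyper$mtry_frac * ncol(X)))
      } else max(1L, floor(sqrt(ncol(X))))
      randomForest::randomForest(
        x = df, y = factor(y, levels = c(0, 1)),
        ntree = hyper$ntree %||% 200, mtry = mtry,
        nodesize = hyper$nodesize %||% 1)
    },
    random_forest_reg = {
      mtry <- if (!is.null(hyper$mtry_frac)) {
        max(1L, floor(hyper$mtry_frac * ncol(X)))
      } else max(1L, floor(ncol(X) / 3))
      randomForest::randomForest(
        x = df, y = y, ntree = hyper$ntree %||% 200, mtry = mtry,
        nodesize = hyper$nodesize %||% 5)
    },
    rpart = {
      d <- df; d$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     cp = hyper$cp %||% 0.01,
                     minsplit = hyper$minsplit %||% 20))
    },
    rpart_reg = {
      d <- df; d$.y <- y
      rpart::rpart(.y ~ ., data = d, method = "anova",
                   control = rpart::rpart.control(
                     cp = hyper$cp %||% 0.01,
                     minsplit = hyper$minsplit %||% 20))
    },
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = hyper$eta %||% 0.3,
                    max_depth = round(hyper$max_depth %||% 6),
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = round(hyper$nrounds %||% 50), verbose = 0),
    xgboost_reg = xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    eta = hyper$eta %||% 0.3,
                    max_depth = round(hyper$max_depth %||% 6),
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = round(hyper$nrounds %||% 50), verbose = 0),
    svm = do.call(e1071::svm, c(
      list(x = X, y = factor(y, levels = c(0, 1)),
           kernel = hyper$kernel %||% "radial",
           cost = hyper$cost %||% 1, scale = FALSE),
      if (!is.null(hyper$gamma)) list(gamma = hyper$gamma),
      if (!is.null(hyper$degree)) list(degree = round(hyper$degree)))),
    svm_reg = do.call(e1071::svm, c(
      list(x = X, y = y, type = "eps-regression",
           kernel = hyper$kernel %||% "radial",
           cost = hyper$cost %||% 1,
           epsilon = hyper$epsilon %||% 0.1, scale = FALSE),
      if (!is.null(hyper$gamma)) list(gamma = hyper$gamma),
      if (!is.null(hyper$degree)) list(degree = round(hyper$degree)))),
    knn = list(train = X, cl = factor(y, levels = c(0, 1)),
               k = round(hyper$k %||% 5), seed = seed),
    glmnet_class = fit_glmnet(X, y, hyper, seed, family = "binomial"),
    glmnet_reg = fit_glmnet(X, y, hyper, seed, family = "gaussian"),
    gausspr = fit_gausspr(X, y, hyper),
    l1_svm_reg = fit_l1_svm(X, y, hyper, seed),
    lm = {
      d <- df; d$.y <- y
      suppressWarnings(stats::lm(.y ~ ., data = d))
    },
    stop("unknown engine '", eng, "'")
  ))
  structure(list(engine = eng, fit = fit, hyper = hyper,
                 features = colnames(X), col_order = names(df)),
            class = "sg_engine")
}

fit_glmnet <- function(X, y, hyper, seed, family) {
  alpha <- hyper$alpha %||% 1
  if (!is.null(hyper$lambda)) {
    f <- suppressWarnings(glmnet::glmnet(X, y, family = family,
                                         alpha = alpha,
                                         lambda = hyper$lambda))
    return(list(fit = f, s = hyper$lambda))
  }
  # defaults mode: pick lambda by a seeded internal 3-fold CV
  foldid <- with_seed(derive_seed(seed, "glmnet_folds"),
                      sample(rep_len(1:3, length(y))))
  cv <- suppressWarnings(glmnet::cv.glmnet(X, y, family = family,
                                           alpha = alpha,
                                           foldid = foldid, nfolds = 3))
  rule <- hyper$lambda_rule %||% "lambda.min"
  list(fit = cv$glmnet.fit, s = cv[[rule]])
}

fit_gausspr <- function(X, y, hyper) {
  kern <- hyper$kernel %||% "rbfdot"
  kpar <- if (!is.null(hyper$sigma)) list(sigma = hyper$sigma) else "automatic"
  suppressMessages(kernlab::gausspr(
    x = X, y = y, type = "regression", kernel = kern, kpar = kpar,
    scaled = FALSE))
}

# L1-regularized SVM regression: lasso picks the active features, a linear
# epsilon-SVM is fitted on them. With an empty active set the model falls
# back to predicting the training mean.
fit_l1_svm <- function(X, y, hyper, seed) {
  g <- fit_glmnet(X, y, c(hyper, list(alpha = 1)), seed, family = "gaussian")
  beta <- as.matrix(stats::coef(g$fit, s = g$s))[-1L, 1L]
  active <- names(beta)[beta != 0]
  active <- intersect(active, colnames(X))
  if (length(active) == 0L) {
    return(list(kind = "mean", mean = mean(y)))
  }
  svm <- e1071::svm(x = X[, active, drop = FALSE], y = y,
                    type = "eps-regression", kernel = "linear",
                    cost = hyper$cost %||% 1, scale = FALSE)
  list(kind = "svm", active = active, svm = svm)
}

predict_engine <- function(model, X) {
  stopifnot(inherits(model, "sg_engine"))
  if (!identical(colnames(X), model$features)) {
    stop("prediction columns do not match the training columns")
  }
  df <- as.data.frame(X)
  names(df) <- model$col_order
  fit <- model$fit
  out <- switch(
    model$engine,
    logistic = suppressWarnings(
      as.numeric(stats::predict(fit, newdata = df, type = "response"))),
    naive_bayes = {
      pr <- stats::predict(fit, newdata = df, type = "raw")
      as.numeric(pr[, "1"])
    },
    random_forest = as.numeric(
      stats::predict(fit, newdata = df, type = "prob")[, "1"]),
    random_forest_reg = as.numeric(stats::predict(fit, newdata = df)),
    rpart = as.numeric(
      stats::predict(fit, newdata = df, type = "prob")[, "1"]),
    rpart_reg = as.numeric(stats::predict(fit, newdata = df)),
    xgboost = as.numeric(stats::predict(
      fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    xgboost_reg = as.numeric(stats::predict(
      fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    svm = {
      p <- stats::predict(fit, X, decision.values = TRUE)
      d <- as.numeric(attr(p, "decision.values"))
      # orientation: the decision-value column name is "A/B", positive
      # favouring class A
      pos <- sub("/.*$", "", colnames(attr(p, "decision.values"))[1L])
      stats::plogis(if (pos == "1") d else -d)
    },
    svm_reg = as.numeric(stats::predict(fit, X)),
    knn = with_seed(derive_seed(fit$seed, "knn_predict"), {
      pr <- class::knn(fit$train, X, fit$cl, k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    }),
    glmnet_class = as.numeric(
      stats::predict(fit$fit, X, s = fit$s, type = "response")),
    glmnet_reg = as.numeric(stats::predict(fit$fit, X, s = fit$s)),
    gausspr = as.numeric(kernlab::predict(fit, X)),
    l1_svm_reg = {
      if (fit$kind == "mean") rep(fit$mean, nrow(X))
      else as.numeric(stats::predict(fit$svm,
                                     X[, fit$active, drop = FALSE]))
    },
    lm = suppressWarnings(as.numeric(stats::predict(fit, newdata = df))),
    stop("unknown engine")
  )
  is_class <- model$engine %in% c("logistic", "naive_bayes", "random_forest",
                                  "rpart", "xgboost", "svm", "knn",
                                  "glmnet_class")
  if (is_class) out <- pmin(pmax(out, 0), 1)
  out
}
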