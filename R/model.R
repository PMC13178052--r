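# Risk models behind a thin interface: a gradient-boosting learner (xgboost,
# histogram method, so the boosting hyperparameters map directly: depth ->
# max_depth, learning_rate -> eta, iterations -> nrounds, l2_leaf_reg ->
# lambda, border_count -> max_bin) and an L2-penalised logistic baseline with
# class-balanced weights (glmnet, alpha = 0). The package's contribution is
# the cross-validation, leakage and search scaffolding, not the learners.

#' Model specification
#'
#' @param family `"boosting"` or `"logistic"`.
#' @param depth,learning_rate,iterations,l2_leaf_reg,border_count boosting
#'   hyperparameters; defaults are the tuned values reported for the study
#'   model (learning_rate 0.083, l2_leaf_reg 25, iterations 900, depth 8,
#'   border_count 30), shipped as a named preset for structural
#'   reproducibility.
#' @param lambda ridge penalty for the logistic baseline.
#' @param seed integer seed.
#' @return object of class `hfgap_model_spec`.
#' @export
model_spec <- function(family = c("boosting", "logistic"),
                       depth = 8, learning_rate = 0.083, iterations = 900,
                       l2_leaf_reg = 25, border_count = 30,
                       lambda = 1e-3, seed = 1L) {
  family <- match.arg(family)
  structure(
    list(family = family, depth = as.integer(depth),
         learning_rate = learning_rate, iterations = as.integer(iterations),
         l2_leaf_reg = l2_leaf_reg, border_count = as.integer(border_count),
         lambda = lambda, seed = as.integer(seed)),
    class = "hfgap_model_spec"
  )
}

fit_learner <- function(spec, x, y) {
  if (spec$family == "boosting") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    params <- list(
      objective = "binary:logistic",
      max_depth = spec$depth,
      eta = spec$learning_rate,
      lambda = spec$l2_leaf_reg,
      max_bin = spec$border_count,
      tree_method = "hist",
      nthread = 1,
      seed = spec$seed
    )
    booster <- xgboost::xgb.train(params, dtrain, nrounds = spec$iterations,
                                  verbose = 0)
    list(kind = "boosting", booster = booster, features = colnames(x))
  } else {
    keep <- apply(x, 2, function(col) stats::sd(col) > 0)
    if (!all(keep)) {
      warning("dropping constant feature(s): ",
              paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
    }
    xk <- x[, keep, drop = FALSE]
    # class-balanced weights: w_i = n / (2 * n_class(i))
    n <- length(y)
    w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
    fit <- glmnet::glmnet(xk, y, family = "binomial", alpha = 0,
                          lambda = spec$lambda, weights = w,
                          standardize = FALSE)
    list(kind = "logistic", fit = fit, features = colnames(xk),
         all_features = colnames(x))
  }
}

predict_learner <- function(learner, x) {
  if (learner$kind == "boosting") {
    as.numeric(stats::predict(learner$booster,
                              xgboost::xgb.DMatrix(x[, learner$features,
                                                     drop = FALSE])))
  } else {
    as.numeric(stats::predict(learner$fit,
                              newx = x[, learner$features, drop = FALSE],
                              type = "response"))
  }
}

#' Stratified k-fold cross-validated training
#'
#' Preprocessing is refit inside each training fold (the function takes a
#' preprocessor *factory*, not a fitted state, so held-out statistics can
#' never leak), per-fold AUC/accuracy/recall/F1 are reported, and a final
#' model is trained on all rows with its own preprocessor.
#'
#' @param features feature tibble with `patient_id` and `label`.
#' @param spec an [model_spec()].
#' @param k number of folds (default 5, stratified by label).
#' @param seed fold-assignment seed.
#' @param preprocessor_factory function `train_features -> state`; defaults to
#'   [fit_preprocessor()] with standardization for the logistic family only.
#' @return object of class `hfgap_model`: `learner`, `state`, `spec`,
#'   `fold_metrics` (tibble), `cv_auc` (mean fold AUC).
#' @export
crossval_train <- function(features, spec, k = 5, seed = 1L,
                           preprocessor_factory = NULL) {
  if (is.null(preprocessor_factory)) {
    preprocessor_factory <- function(train) {
      fit_preprocessor(train, standardize = spec$family == "logistic")
    }
  }
  y_all <- as.integer(features$label == "HF")
  if (k > min(table(y_all))) {
    stop("k exceeds the minority-class count", call. = FALSE)
  }
  fold <- stratified_folds(y_all, k, seed)
  metrics <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- features[fold != f, , drop = FALSE]
    te <- features[fold == f, , drop = FALSE]
    state <- preprocessor_factory(tr)
    ptr <- apply_preprocessor(state, tr)
    pte <- apply_preprocessor(state, te)
    learner <- fit_learner(spec, ptr$x, ptr$label)
    scores <- predict_learner(learner, pte$x)
    rep <- confusion_and_rates(scores, pte$label)
    tibble::tibble(fold = f, auc = roc_auc(scores, pte$label),
                   accuracy = rep$accuracy, recall = rep$recall, f1 = rep$f1)
  })
  state <- preprocessor_factory(features)
  pall <- apply_preprocessor(state, features)
  learner <- fit_learner(spec, pall$x, pall$label)
  structure(
    list(learner = learner, state = state, spec = spec,
         fold_metrics = metrics, cv_auc = mean(metrics$auc),
         folds = fold),
    class = "hfgap_model"
  )
}

#' Predicted HF probabilities
#'
#' Applies the model's own preprocessor state and returns one score in
#' `[0, 1]` per row; deterministic given model and input.
#'
#' @param model an `hfgap_model` from [crossval_train()] or
#'   [fit_logistic_baseline()].
#' @param features feature tibble.
#' @return numeric vector of probabilities.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "hfgap_model"))
  missing <- setdiff(
    c(names(model$state$medians), names(model$state$modes)),
    names(features))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- apply_preprocessor(model$state, features)
  predict_learner(model$learner, p$x)
}

#' L2-penalised logistic baseline
#'
#' Convenience wrapper: [crossval_train()] with the logistic family
#' (standardized predictors, class-balanced weights).
#'
#' @inheritParams crossval_train
#' @param lambda ridge penalty.
#' @return `hfgap_model`.
#' @export
fit_logistic_baseline <- function(features, k = 5, seed = 1L, lambda = 1e-3) {
  crossval_train(features, model_spec("logistic", lambda = lambda, seed = seed),
                 k = k, seed = seed)
}

#' Hyperparameter search spaces
#'
#' The broad first-stage space (random search: depth 1--10, learning_rate
#' 0.01--1, iterations 100--1000, l2_leaf_reg 2--100, border_count 10--35) and
#' the narrowed second-stage space (depth 5--10 integer, learning_rate
#' 0.01--0.5 log-uniform, iterations 500--1000 integer, l2_leaf_reg 2--35
#' log-uniform, border_count 10--35 integer).
#'
#' @param stage `"random"` or `"bayesian"`.
#' @return list of per-parameter ranges with sampling scales.
#' @export
search_space <- function(stage = c("random", "bayesian")) {
  stage <- match.arg(stage)
  if (stage == "random") {
    list(
      depth = list(range = c(1, 10), type = "integer"),
      learning_rate = list(range = c(0.01, 1), type = "uniform"),
      iterations = list(range = c(100, 1000), type = "integer"),
      l2_leaf_reg = list(range = c(2, 100), type = "uniform"),
      border_count = list(range = c(10, 35), type = "integer")
    )
  } else {
    list(
      depth = list(range = c(5, 10), type = "integer"),
      learning_rate = list(range = c(0.01, 0.5), type = "log-uniform"),
      iterations = list(range = c(500, 1000), type = "integer"),
      l2_leaf_reg = list(range = c(2, 35), type = "log-uniform"),
      border_count = list(range = c(10, 35), type = "integer")
    )
  }
}

sample_from_space <- function(space, n) {
  draws <- lapply(space, function(par) {
    r <- par$range
    switch(par$type,
           integer = sample(seq(r[1], r[2]), n, replace = TRUE),
           uniform = stats::runif(n, r[1], r[2]),
           `log-uniform` = exp(stats::runif(n, log(r[1]), log(r[2]))))
  })
  tibble::as_tibble(draws)
}

#' Two-stage hyperparameter search
#'
#' Stage 1 samples uniformly (or log-uniformly, where declared) from the broad
#' random-search space and scores each draw by mean cross-validated AUC.
#' Stage 2 refines inside the narrowed space, warm-started from the stage-1
#' trace: at each iteration a random-forest surrogate fitted to the trace
#' predicts the AUC of a pool of candidate draws and the best-predicted
#' candidate is evaluated.
#'
#' @param features feature tibble with `patient_id` and `label`.
#' @param budget_random,budget_bayes evaluations per stage (>= 1).
#' @param k cross-validation folds per evaluation.
#' @param seed search seed.
#' @param n_candidates surrogate candidate-pool size per refinement step.
#' @return list with `best_spec` (an [model_spec()]), `best_auc`, and `trace`
#'   (tibble of every evaluated configuration with its stage and mean AUC).
#' @export
two_stage_search <- function(features, budget_random = 10, budget_bayes = 10,
                             k = 5, seed = 1L, n_candidates = 50) {
  stopifnot(budget_random >= 1, budget_bayes >= 1)
  evaluate <- function(par, i) {
    spec <- model_spec("boosting", depth = par$depth,
                       learning_rate = par$learning_rate,
                       iterations = par$iterations,
                       l2_leaf_reg = par$l2_leaf_reg,
                       border_count = par$border_count,
                       seed = derive_seed(seed, paste0("eval", i)))
    fit <- crossval_train(features, spec, k = k,
                          seed = derive_seed(seed, "folds"))
    fit$cv_auc
  }
  par_cols <- c("depth", "learning_rate", "iterations", "l2_leaf_reg",
                "border_count")

  set.seed(derive_seed(seed, "stage1"))
  stage1 <- sample_from_space(search_space("random"), budget_random)
  stage1$auc <- vapply(seq_len(budget_random), function(i) {
    evaluate(stage1[i, ], i)
  }, numeric(1))
  stage1$stage <- "random"

  trace <- stage1
  set.seed(derive_seed(seed, "stage2"))
  bayes_space <- search_space("bayesian")
  for (j in seq_len(budget_bayes)) {
    candidates <- sample_from_space(bayes_space, n_candidates)
    if (nrow(trace) >= 5) {
      surrogate <- randomForest::randomForest(
        x = as.data.frame(trace[, par_cols]), y = trace$auc, ntree = 200)
      pred <- stats::predict(surrogate, as.data.frame(candidates))
      pick <- candidates[which.max(pred), ]
    } else {
      pick <- candidates[1, ]
    }
    pick$auc <- evaluate(pick, budget_random + j)
    pick$stage <- "bayesian"
    trace <- dplyr::bind_rows(trace, pick)
  }

  best <- trace[which.max(trace$auc), ]
  best_spec <- model_spec("boosting", depth = best$depth,
                          learning_rate = best$learning_rate,
                          iterations = best$iterations,
                          l2_leaf_reg = best$l2_leaf_reg,
                          border_count = best$border_count, seed = seed)
  list(best_spec = best_spec, best_auc = best$auc, trace = trace)
}
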