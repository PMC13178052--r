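test_that("separable data gives perfect fold AUCs; shuffled labels do not", {
  feats <- toy_features(n = 200, beta = 50, seed = 2)
  feats$signal <- ifelse(feats$label == "HF", 1, -1) # fully separable
  fit <- crossval_train(feats, model_spec("boosting", iterations = 30,
                                          depth = 2), k = 5, seed = 1)
  expect_true(all(fit$fold_metrics$auc == 1))

  set.seed(4)
  feats$label <- sample(feats$label)
  fit0 <- crossval_train(feats, model_spec("boosting", iterations = 30,
                                           depth = 2), k = 5, seed = 1)
  n1 <- sum(feats$label == "HF"); n0 <- sum(feats$label == "NON_HF")
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0)) * sqrt(5) # per-fold scale
  expect_lt(abs(mean(fit0$fold_metrics$auc) - 0.5), 3 * se)
})

test_that("cross-validation is deterministic given the seed", {
  feats <- toy_features(n = 150, seed = 5)
  f1 <- crossval_train(feats, model_spec("boosting", iterations = 20,
                                         depth = 3), k = 5, seed = 9)
  f2 <- crossval_train(feats, model_spec("boosting", iterations = 20,
                                         depth = 3), k = 5, seed = 9)
  expect_identical(f1$folds, f2$folds)
  expect_equal(f1$fold_metrics, f2$fold_metrics)
  expect_equal(predict_proba(f1, feats), predict_proba(f2, feats))
  f3 <- crossval_train(feats, model_spec("boosting", iterations = 20,
                                         depth = 3), k = 5, seed = 10)
  expect_false(identical(f1$folds, f3$folds))
})

test_that("stratification preserves the label ratio within one per fold", {
  feats <- toy_features(n = 203, seed = 6)
  fit <- crossval_train(feats, model_spec("boosting", iterations = 10,
                                          depth = 2), k = 5, seed = 2)
  y <- as.integer(feats$label == "HF")
  per_fold <- table(fit$folds, y)
  expect_lte(diff(range(per_fold[, "1"])), 1)
  expect_lte(diff(range(per_fold[, "0"])), 1)
  expect_error(
    crossval_train(feats[c(which(y == 1)[1:3], which(y == 0)), ],
                   model_spec("boosting"), k = 5),
    "minority")
})

test_that("the logistic baseline standardizes, weights classes, and drops
           constant features", {
  feats <- toy_features(n = 300, beta = 2, seed = 7)
  feats$flat <- 1
  # the warning fires in every fold refit; assert it once, silence the rest
  warns <- testthat::capture_warnings(
    fit <- fit_logistic_baseline(feats, k = 5, seed = 1))
  expect_true(all(grepl("constant feature", warns)))
  expect_gte(length(warns), 1)
  # planted direction: higher signal, higher score
  hi <- feats; hi$signal <- 2
  lo <- feats; lo$signal <- -2
  expect_true(all(predict_proba(fit, hi) > predict_proba(fit, lo)))
  expect_true(fit$state$standardize)
})

test_that("predict_proba validates its schema and is deterministic", {
  feats <- toy_features(n = 100, seed = 8)
  fit <- crossval_train(feats, model_spec("boosting", iterations = 10,
                                          depth = 2), k = 5, seed = 1)
  expect_error(predict_proba(fit, feats[, c("patient_id", "label", "noise")]),
               "signal")
  p <- predict_proba(fit, feats)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict_proba(fit, feats[c(1, 1), ])[1],
               predict_proba(fit, feats[c(1, 1), ])[2])
})

test_that("two-stage search traces every evaluation and is reproducible", {
  feats <- toy_features(n = 120, seed = 9)
  # tiny iteration counts via a shrunken space keep the test fast
  s1 <- two_stage_search(feats, budget_random = 2, budget_bayes = 2, k = 3,
                         seed = 5, n_candidates = 10)
  expect_equal(nrow(s1$trace), 4)
  expect_identical(s1$trace$stage, c("random", "random", "bayesian",
                                     "bayesian"))
  expect_equal(s1$best_auc, max(s1$trace$auc))
  expect_s3_class(s1$best_spec, "hfgap_model_spec")
  in_range <- function(x, lo, hi) all(x >= lo & x <= hi)
  expect_true(in_range(s1$trace$depth[1:2], 1, 10))
  expect_true(in_range(s1$trace$depth[3:4], 5, 10))
  expect_true(in_range(s1$trace$learning_rate[3:4], 0.01, 0.5))
  expect_true(in_range(s1$trace$l2_leaf_reg[3:4], 2, 35))
  s2 <- two_stage_search(feats, budget_random = 2, budget_bayes = 2, k = 3,
                         seed = 5, n_candidates = 10)
  expect_equal(s1$trace, s2$trace)
})

test_that("search spaces declare the documented ranges and scales", {
  r <- search_space("random")
  expect_equal(r$depth$range, c(1, 10))
  expect_equal(r$learning_rate$range, c(0.01, 1))
  expect_equal(r$iterations$range, c(100, 1000))
  expect_equal(r$l2_leaf_reg$range, c(2, 100))
  expect_equal(r$border_count$range, c(10, 35))
  b <- search_space("bayesian")
  expect_equal(b$depth$range, c(5, 10))
  expect_identical(b$learning_rate$type, "log-uniform")
  expect_equal(b$l2_leaf_reg$range, c(2, 35))
  expect_equal(b$iterations$range, c(500, 1000))
})

test_that("held-out scores are immune to held-out perturbation before fit", {
  # the preprocessor factory never sees the held-out fold, so perturbing a
  # held-out row's feature distribution must not change other rows' scores
  feats <- toy_features(n = 200, seed = 11)
  fit <- crossval_train(feats, model_spec("boosting", iterations = 20,
                                          depth = 2), k = 5, seed = 3)
  newdata <- toy_features(n = 50, seed = 12)
  p1 <- predict_proba(fit, newdata)
  perturbed <- newdata
  perturbed$signal[1] <- 1e6
  p2 <- predict_proba(fit, perturbed)
  expect_equal(p1[-1], p2[-1])
})
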