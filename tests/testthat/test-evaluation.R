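test_that("roc_auc equals the pairwise concordance oracle, ties included", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(c(1, 2), 1)) # induce ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- runif(500)
  labels <- rbinom(500, 1, plogis(3 * (scores - 0.5)))
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("confusion rates behave at thresholds and under class imbalance", {
  r <- confusion_and_rates(c(0.9, 0.1), c(1, 0))
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  # the accuracy trap: all-negative predictions at 2% prevalence
  n <- 1000
  labels <- c(rep(1, 20), rep(0, 980))
  r2 <- confusion_and_rates(rep(0.1, n), labels, threshold = 0.5)
  expect_equal(r2$accuracy, 0.98)
  expect_equal(r2$recall, 0)
  expect_true(is.na(r2$precision)) # zero denominator reported as NA
  r3 <- confusion_and_rates(rep(0.1, n), labels, threshold = 0)
  expect_equal(r3$recall, 1)
})

test_that("brier matches its closed form for constant predictors", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  set.seed(23)
  for (rep in 1:10) {
    p <- runif(1)
    pi <- runif(1, 0.2, 0.8)
    n <- 400
    labels <- rbinom(n, 1, pi)
    pi_hat <- mean(labels)
    expect_equal(brier(rep(p, n), labels),
                 p^2 * (1 - pi_hat) + (1 - p)^2 * pi_hat)
  }
})

test_that("ece and mce follow their definitions and ordering", {
  expect_equal(ece_mce(c(0, 1, 1, 0), c(0, 1, 1, 0))$ece, 0)
  labels <- rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 30) # prevalence 0.1
  cal <- ece_mce(rep(0.1, 300), labels)
  expect_equal(cal$ece, 0)
  expect_equal(cal$mce, 0)
  # independent re-binning oracle on random small sets
  set.seed(24)
  for (rep in 1:10) {
    n <- 200
    scores <- runif(n)
    labs <- rbinom(n, 1, scores)
    got <- ece_mce(scores, labs, n_bins = 10)
    bin <- pmin(floor(scores * 10) + 1, 10)
    gaps <- vapply(sort(unique(bin)), function(b) {
      abs(mean(scores[bin == b]) - mean(labs[bin == b]))
    }, numeric(1))
    ns <- vapply(sort(unique(bin)), function(b) sum(bin == b), numeric(1))
    expect_equal(got$ece, sum(ns / n * gaps))
    expect_equal(got$mce, max(gaps))
    expect_lte(got$ece, got$mce)
  }
})

test_that("calibration slope detects overconfident predictions", {
  set.seed(25)
  p <- runif(20000, 0.05, 0.95)
  labels <- rbinom(20000, 1, p)
  well <- calibration_slope_intercept(p, labels)
  expect_lt(abs(well$slope - 1), 0.1)
  expect_lt(abs(well$intercept), 0.1)
  over <- calibration_slope_intercept(p^2, labels)
  expect_lt(over$slope, 1)
  expect_error(calibration_slope_intercept(rep(0.5, 100), rbinom(100, 1, 0.5)),
               "degenerate")
})

test_that("hosmer-lemeshow flags gross miscalibration, not calibrated scores", {
  set.seed(26)
  p <- runif(5000, 0.05, 0.95)
  labels <- rbinom(5000, 1, p)
  hl_bad <- hosmer_lemeshow(1 - p, labels)
  expect_lt(hl_bad$pvalue, 0.001)
  hl_ok <- hosmer_lemeshow(p, labels)
  expect_gt(hl_ok$pvalue, 0.001)
  expect_equal(hl_ok$df, 8)
})

test_that("degenerate risk groups are merged into a neighbour", {
  set.seed(27)
  scores <- c(rep(0, 200), runif(300, 0.2, 0.9))
  labels <- c(rep(0, 200), rbinom(300, 1, scores[201:500]))
  expect_message(hl <- hosmer_lemeshow(scores, labels), "merged")
  expect_true(is.finite(hl$statistic))
  expect_equal(hl$df, nrow(hl$table) - 2)
})

test_that("learning curve shows train optimism and uses a fixed validation", {
  pop <- generate_population(signal_config(4000, seed = 31))
  cs <- default_codesets()
  amb <- classify_ambulatory(pop$events, cs$ambulatory_icds,
                             cs$ambulatory_procedures,
                             patient_ids = pop$demographics$patient_id)
  labels <- tibble::tibble(
    patient_id = amb$patient_id,
    label = ifelse(amb$label == "DIAGNOSED_HF", "HF", "NON_HF"))
  feats <- build_features(pop$events, pop$demographics, labels)
  lc <- learning_curve(feats, model_spec("boosting", iterations = 40,
                                         depth = 3),
                       train_fractions = c(0.2, 1), seed = 2)
  expect_equal(nrow(lc), 2)
  expect_true(all(lc$train_auc >= lc$val_auc - 0.02))
  expect_gt(lc$val_auc[2], 0.6) # signal present, model learns it
})

test_that("permutation importance isolates the informative feature", {
  feats <- toy_features(n = 400, beta = 3, seed = 32)
  fit <- crossval_train(feats, model_spec("boosting", iterations = 40,
                                          depth = 3), k = 5, seed = 1)
  imp <- permutation_importance(fit, feats, n_repeats = 3, seed = 4)
  sig <- imp$importance[imp$feature == "signal"]
  noi <- imp$importance[imp$feature == "noise"]
  expect_gt(sig, 0.1)
  expect_lt(abs(noi), 0.05)
  imp2 <- permutation_importance(fit, feats, n_repeats = 3, seed = 4)
  expect_equal(imp, imp2)
})
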