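# Discrimination and calibration metrics implemented from their defining
# formulas (rank-based AUC, Brier, equal-width-bin ECE/MCE, grouped Pearson
# Hosmer-Lemeshow with df = g - 2, logistic recalibration slope/intercept),
# plus learning curves and permutation importance.

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form of the trapezoidal AUC: the probability that a
#' random case outscores a random control, ties counting one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and derived rates at a threshold
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param threshold classification threshold (default 0.5; `score >=
#'   threshold` predicts positive).
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `recall`,
#'   `precision`, `f1`, `specificity`, `npv`. Rates with zero denominators
#'   are `NA`, not zero.
#' @export
confusion_and_rates <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = div(tp + tn, tp + fp + tn + fn),
       recall = recall, precision = precision, f1 = f1,
       specificity = div(tn, tn + fp), npv = div(tn, tn + fn))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and observed outcome.
#'
#' @inheritParams confusion_and_rates
#' @return Brier score in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  stopifnot(all(scores >= 0 & scores <= 1))
  mean((scores - as.numeric(labels))^2)
}

#' Expected and maximum calibration error
#'
#' ECE is the bin-size-weighted mean absolute gap between mean predicted
#' probability and observed event rate; MCE is the maximum gap over non-empty
#' bins. Empty bins are skipped.
#'
#' @inheritParams confusion_and_rates
#' @param n_bins number of bins (>= 2).
#' @param scheme `"equal_width"` (default) or `"quantile"`.
#' @return list with `ece`, `mce`, and `curve` (tibble of bin mean predicted,
#'   observed rate, n).
#' @export
ece_mce <- function(scores, labels, n_bins = 10,
                    scheme = c("equal_width", "quantile")) {
  scheme <- match.arg(scheme)
  stopifnot(n_bins >= 2)
  labels <- as.numeric(labels)
  breaks <- if (scheme == "equal_width") {
    seq(0, 1, length.out = n_bins + 1)
  } else {
    unique(stats::quantile(scores, seq(0, 1, length.out = n_bins + 1)))
  }
  bin <- cut(scores, breaks, include.lowest = TRUE, labels = FALSE)
  curve <- tibble::tibble(bin = bin, score = scores, label = labels) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_predicted = mean(.data$score),
                     observed_rate = mean(.data$label),
                     n = dplyr::n(), .groups = "drop")
  gaps <- abs(curve$mean_predicted - curve$observed_rate)
  list(ece = sum(curve$n / length(scores) * gaps),
       mce = max(gaps),
       curve = curve)
}

#' Calibration slope and intercept
#'
#' Maximum-likelihood logistic regression of outcomes on logit-transformed
#' predictions: `label ~ a + b * logit(score)`. A slope of 1 and intercept of
#' 0 indicate ideal calibration. Also reports calibration-in-the-large (the
#' intercept with the slope fixed at 1).
#'
#' @inheritParams confusion_and_rates
#' @param clip scores are clipped to `[clip, 1 - clip]` before the logit.
#' @return list with `slope`, `intercept`, `calibration_in_the_large`.
#' @export
calibration_slope_intercept <- function(scores, labels, clip = 1e-6) {
  lp <- logit(clip01(scores, clip))
  if (stats::sd(lp) == 0) {
    stop("degenerate design: all scores identical", call. = FALSE)
  }
  labels <- as.integer(labels)
  fit <- stats::glm(labels ~ lp, family = stats::binomial())
  if (!fit$converged) stop("recalibration fit did not converge", call. = FALSE)
  citl <- stats::glm(labels ~ 1 + offset(lp), family = stats::binomial())
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       calibration_in_the_large = unname(stats::coef(citl)[1]))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into deciles of predicted risk (score quantiles, ties
#' kept together), computes the grouped Pearson statistic
#' `sum (O_g - E_g)^2 / (E_g (1 - E_g / n_g))`, and refers it to a chi-square
#' reference. For probabilities estimated on the same data the reference has
#' `groups - 2` degrees of freedom (the default); for externally supplied
#' probabilities -- a validation sample scored by a model fitted elsewhere --
#' the appropriate reference has `groups` degrees of freedom (the
#' D'Agostino-Nam convention), which is what holds the test at its nominal
#' size in simulation. Groups with expected counts of 0 or n are merged into
#' a neighbour.
#'
#' @inheritParams confusion_and_rates
#' @param groups number of risk groups (default 10, >= 3).
#' @param external if `TRUE`, the scores were not estimated from `labels`'
#'   own data and the chi-square reference uses `groups` degrees of freedom.
#' @return list with `statistic`, `df`, `pvalue`, `table` (per-group observed
#'   and expected counts).
#' @export
hosmer_lemeshow <- function(scores, labels, groups = 10, external = FALSE) {
  stopifnot(groups >= 3)
  labels <- as.numeric(labels)
  qs <- unique(stats::quantile(scores, seq(0, 1, length.out = groups + 1)))
  grp <- cut(scores, qs, include.lowest = TRUE, labels = FALSE)
  tab <- tibble::tibble(grp = grp, score = scores, label = labels) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(n = dplyr::n(), observed = sum(.data$label),
                     expected = sum(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$grp)
  # merge degenerate groups (expected 0 or n) into the previous neighbour
  i <- 1
  while (i <= nrow(tab)) {
    if (tab$expected[i] <= 0 || tab$expected[i] >= tab$n[i]) {
      j <- if (i == 1) 2 else i - 1
      if (j > nrow(tab)) break
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab <- tab[-i, ]
      message("merged a degenerate risk group into its neighbour")
      i <- max(i - 1, 1)
    } else {
      i <- i + 1
    }
  }
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- if (external) nrow(tab) else nrow(tab) - 2
  list(statistic = stat, df = df,
       pvalue = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Full calibration report
#'
#' @inheritParams ece_mce
#' @param groups Hosmer-Lemeshow groups.
#' @return list combining [brier()], [ece_mce()], [hosmer_lemeshow()] and
#'   [calibration_slope_intercept()] with the binning scheme recorded.
#' @export
calibration_report <- function(scores, labels, n_bins = 10,
                               scheme = "equal_width", groups = 10) {
  em <- ece_mce(scores, labels, n_bins, scheme)
  hl <- hosmer_lemeshow(scores, labels, groups)
  si <- calibration_slope_intercept(scores, labels)
  list(brier = brier(scores, labels), ece = em$ece, mce = em$mce,
       curve = em$curve, hl_statistic = hl$statistic, hl_df = hl$df,
       hl_pvalue = hl$pvalue, slope = si$slope, intercept = si$intercept,
       calibration_in_the_large = si$calibration_in_the_large,
       binning_scheme = scheme, n_bins = n_bins)
}

#' Learning curve
#'
#' Trains on stratified subsamples of the training partition at the requested
#' fractions and evaluates each model on the same fixed validation partition.
#'
#' @param features feature tibble with `patient_id` and `label`.
#' @param spec an [model_spec()].
#' @param train_fractions fractions of the training partition to use.
#' @param seed split/subsample seed.
#' @param val_fraction share held out as the fixed validation partition.
#' @return tibble with `fraction`, `n_train`, `train_auc`, `val_auc`.
#' @export
learning_curve <- function(features, spec, train_fractions = c(0.2, 0.5, 1),
                           seed = 1L, val_fraction = 0.2) {
  stopifnot(all(train_fractions > 0 & train_fractions <= 1))
  y <- as.integer(features$label == "HF")
  set.seed(derive_seed(seed, "lc_split"))
  val_idx <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(val_fraction * length(idx)))
  }))
  val <- features[val_idx, , drop = FALSE]
  train <- features[-val_idx, , drop = FALSE]
  ytr <- y[-val_idx]
  purrr::map_dfr(train_fractions, function(fr) {
    set.seed(derive_seed(seed, paste0("lc_", fr)))
    sub_idx <- unlist(lapply(unique(ytr), function(cl) {
      idx <- which(ytr == cl)
      sample(idx, max(2, round(fr * length(idx))))
    }))
    sub <- train[sub_idx, , drop = FALSE]
    state <- fit_preprocessor(sub, standardize = spec$family == "logistic")
    psub <- apply_preprocessor(state, sub)
    pval <- apply_preprocessor(state, val)
    learner <- fit_learner(spec, psub$x, psub$label)
    tibble::tibble(
      fraction = fr, n_train = nrow(sub),
      train_auc = roc_auc(predict_learner(learner, psub$x), psub$label),
      val_auc = roc_auc(predict_learner(learner, pval$x), pval$label)
    )
  })
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean drop in the evaluation metric over
#' `n_repeats` random shuffles of that feature column, model held fixed.
#'
#' @param model an `hfgap_model`.
#' @param features feature tibble with `label`.
#' @param feature_names columns to assess (default: all feature columns).
#' @param metric function `(scores, labels) -> value`; default [roc_auc()].
#' @param n_repeats shuffles per feature.
#' @param seed shuffle seed.
#' @return tibble with `feature`, `importance` (mean metric drop), `sd`.
#' @export
permutation_importance <- function(model, features, feature_names = NULL,
                                   metric = roc_auc, n_repeats = 5,
                                   seed = 1L) {
  labels <- as.integer(features$label == "HF")
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(features), c("patient_id", "label"))
  }
  baseline <- metric(predict_proba(model, features), labels)
  set.seed(derive_seed(seed, "permimp"))
  purrr::map_dfr(feature_names, function(fn) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      shuffled <- features
      shuffled[[fn]] <- sample(shuffled[[fn]])
      baseline - metric(predict_proba(model, shuffled), labels)
    }, numeric(1))
    tibble::tibble(feature = fn, importance = mean(drops),
                   sd = stats::sd(drops))
  })
}
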