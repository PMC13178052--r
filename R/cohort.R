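# Leakage-safe cohort construction: completeness and plausibility filters,
# the 12-month washout window, windowed count features, fold-safe
# preprocessing, and balanced / validation / low-prevalence cohort assembly.

#' Completeness filter on demographics
#'
#' Retains exactly the patients with all five mandatory fields (age, sex,
#' weight, height, race) present.
#'
#' @param demographics tibble (see [read_demographics()]).
#' @return character vector of retained patient ids.
#' @export
completeness_filter <- function(demographics) {
  keep <- stats::complete.cases(
    demographics[, c("age", "sex", "race", "height", "weight")])
  if (!any(keep)) warning("no patient passes the completeness filter",
                          call. = FALSE)
  demographics$patient_id[keep]
}

#' Apply the 12-month washout window to events
#'
#' For patients with a first I50 date (cases), only events dated at least
#' `washout_days` before that date are kept; for patients without one
#' (controls), or optionally relative to a supplied pseudo-index date, the
#' full window applies. Events after `feature_end_year` are always dropped
#' (no records from the labelling year feed the features).
#'
#' @param events tibble of ambulatory events.
#' @param index_dates tibble with `patient_id` and `index_date` (the first
#'   I50 date for cases, `NA` for controls -- or a matched pseudo-index for
#'   controls when exploring truncation bias).
#' @param washout_days washout length in days (default 365; "at least 12
#'   months before" is implemented as `event_date <= index_date - 365`,
#'   inclusive, calendar-day arithmetic).
#' @param feature_end_year last calendar year whose events may be used
#'   (default 2021).
#' @return filtered events; attribute `zero_event_patients` lists case ids
#'   whose events were all removed (they stay in the cohort with zero counts).
#' @export
apply_washout <- function(events, index_dates, washout_days = 365,
                          feature_end_year = 2021) {
  ev <- dplyr::left_join(events, index_dates, by = "patient_id")
  kept <- ev |>
    dplyr::filter(
      as.integer(format(.data$event_date, "%Y")) <= feature_end_year,
      is.na(.data$index_date) |
        .data$event_date <= .data$index_date - washout_days
    ) |>
    dplyr::select(-"index_date")
  cases <- index_dates$patient_id[!is.na(index_dates$index_date)]
  zero <- setdiff(cases, unique(kept$patient_id))
  if (length(zero)) {
    message(length(zero),
            " case(s) retained with zero events after washout")
  }
  attr(kept, "zero_event_patients") <- zero
  kept
}

#' Build per-patient feature vectors from windowed events
#'
#' Aggregates event counts per 3-character ICD prefix (`code_*` columns),
#' per ICD-10 chapter (`chapter_*`), and per procedure (`proc_*`), joined to
#' demographics. Patients present in `demographics` but with no surviving
#' events receive all-zero counts.
#'
#' @param events washout-filtered events ([apply_washout()]).
#' @param demographics demographics tibble (defines the patient universe).
#' @param labels optional tibble `patient_id`, `label` (`"HF"`/`"NON_HF"`).
#' @return tibble, one row per patient.
#' @export
build_features <- function(events, demographics, labels = NULL) {
  code_counts <- events |>
    dplyr::mutate(code = substr(.data$icd10, 1, 3)) |>
    dplyr::count(.data$patient_id, .data$code) |>
    tidyr::pivot_wider(names_from = "code", values_from = "n",
                       values_fill = 0, names_prefix = "code_")
  chapter_counts <- events |>
    dplyr::mutate(chapter = icd_chapter(.data$icd10)) |>
    dplyr::count(.data$patient_id, .data$chapter) |>
    tidyr::pivot_wider(names_from = "chapter", values_from = "n",
                       values_fill = 0, names_prefix = "chapter_")
  proc_counts <- events |>
    dplyr::filter(!is.na(.data$procedure)) |>
    dplyr::count(.data$patient_id, .data$procedure) |>
    tidyr::pivot_wider(names_from = "procedure", values_from = "n",
                       values_fill = 0, names_prefix = "proc_")
  out <- demographics |>
    dplyr::left_join(code_counts, by = "patient_id") |>
    dplyr::left_join(chapter_counts, by = "patient_id") |>
    dplyr::left_join(proc_counts, by = "patient_id")
  count_cols <- grep("^(code_|chapter_|proc_)", names(out), value = TRUE)
  for (cc in count_cols) {
    out[[cc]][is.na(out[[cc]])] <- 0
  }
  if (!is.null(labels)) out <- dplyr::inner_join(out, labels, by = "patient_id")
  out
}

#' Fit preprocessing state on a training partition
#'
#' Computes, from the training rows only: per-feature medians (continuous) and
#' modes (categorical) for imputation, 99th-percentile caps for count columns,
#' and means/SDs for optional standardization. Applying the state to any
#' partition never consults that partition's statistics.
#'
#' @param train training feature tibble (from [build_features()]).
#' @param standardize if `TRUE`, continuous features are standardized on
#'   apply (linear-model path); tree models use raw cleaned values.
#' @return object of class `hfgap_preprocessor`.
#' @export
fit_preprocessor <- function(train, standardize = FALSE) {
  num_cols <- names(train)[vapply(train, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "label")
  cat_cols <- setdiff(
    names(train)[vapply(train, is.character, logical(1))],
    c("patient_id", "label"))
  count_cols <- grep("^(code_|chapter_|proc_)", num_cols, value = TRUE)

  medians <- vapply(num_cols, function(cc) {
    m <- stats::median(train[[cc]], na.rm = TRUE)
    if (is.na(m)) stop("feature entirely missing in training: ", cc,
                       call. = FALSE)
    m
  }, numeric(1))
  modes <- vapply(cat_cols, function(cc) {
    tab <- sort(table(train[[cc]]), decreasing = TRUE)
    if (length(tab) == 0) stop("feature entirely missing in training: ", cc,
                               call. = FALSE)
    names(tab)[1]
  }, character(1))
  caps <- vapply(count_cols, function(cc) {
    stats::quantile(train[[cc]], 0.99, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  levels <- lapply(cat_cols, function(cc) sort(unique(
    train[[cc]][!is.na(train[[cc]])])))
  names(levels) <- cat_cols
  means <- vapply(num_cols, function(cc) mean(train[[cc]], na.rm = TRUE),
                  numeric(1))
  sds <- vapply(num_cols, function(cc) {
    s <- stats::sd(train[[cc]], na.rm = TRUE)
    if (is.na(s) || s == 0) 1 else s
  }, numeric(1))

  structure(
    list(medians = as.list(medians), modes = as.list(modes),
         caps = as.list(caps), levels = levels,
         means = as.list(means), sds = as.list(sds),
         standardize = standardize),
    class = "hfgap_preprocessor"
  )
}

#' Plausibility filter
#'
#' Drops patients with implausible eligibility variables (age outside
#' 18--110 years, BMI outside 12--60 kg/m^2) and sets count features above the
#' training 99th percentile to missing (to be median-imputed), treating them
#' as probable coding or data-entry errors.
#'
#' @param features feature tibble.
#' @param state fitted [fit_preprocessor()] state (supplies the p99 caps).
#' @param drop_outlier_patients if `TRUE`, drop the whole patient instead of
#'   setting the offending count to missing.
#' @return filtered feature tibble.
#' @export
plausibility_filter <- function(features, state, drop_outlier_patients = FALSE) {
  keep <- rep(TRUE, nrow(features))
  if ("age" %in% names(features)) {
    keep <- keep & (is.na(features$age) |
                      (features$age >= 18 & features$age <= 110))
  }
  if ("bmi" %in% names(features)) {
    keep <- keep & (is.na(features$bmi) |
                      (features$bmi >= 12 & features$bmi <= 60))
  }
  out <- features[keep, , drop = FALSE]
  for (cc in names(state$caps)) {
    if (!cc %in% names(out)) next
    over <- !is.na(out[[cc]]) & out[[cc]] > state$caps[[cc]]
    if (drop_outlier_patients) {
      out <- out[!over, , drop = FALSE]
    } else {
      out[[cc]][over] <- NA
    }
  }
  out
}

#' Apply a fitted preprocessor
#'
#' Imputes missing continuous values with training medians and categorical
#' values with training modes, one-hot encodes categoricals against the
#' training levels, and (when the state requests it) standardizes continuous
#' features with training means/SDs.
#'
#' @param state [fit_preprocessor()] state.
#' @param features feature tibble.
#' @return list with `x` (numeric model matrix), `patient_id`, and `label`
#'   (if present, as 0/1 with HF = 1).
#' @export
apply_preprocessor <- function(state, features) {
  out <- features
  for (cc in names(state$medians)) {
    if (!cc %in% names(out)) out[[cc]] <- state$medians[[cc]]
    out[[cc]][is.na(out[[cc]])] <- state$medians[[cc]]
  }
  for (cc in names(state$modes)) {
    if (!cc %in% names(out)) out[[cc]] <- state$modes[[cc]]
    out[[cc]][is.na(out[[cc]])] <- state$modes[[cc]]
  }
  num_cols <- names(state$medians)
  if (state$standardize) {
    for (cc in num_cols) {
      out[[cc]] <- (out[[cc]] - state$means[[cc]]) / state$sds[[cc]]
    }
  }
  mats <- list(as.matrix(out[, num_cols, drop = FALSE]))
  for (cc in names(state$levels)) {
    lev <- state$levels[[cc]]
    onehot <- vapply(lev, function(lv) as.numeric(out[[cc]] == lv),
                     numeric(nrow(out)))
    if (nrow(out) == 1) onehot <- matrix(onehot, nrow = 1)
    colnames(onehot) <- paste0(cc, "_", lev)
    mats <- c(mats, list(onehot))
  }
  x <- do.call(cbind, mats)
  rownames(x) <- NULL
  label <- NULL
  if ("label" %in% names(features)) {
    label <- as.integer(features$label == "HF")
  }
  list(x = x, patient_id = features$patient_id, label = label)
}

#' Serialize / restore preprocessor state as JSON
#'
#' @param state [fit_preprocessor()] state.
#' @param path JSON file path.
#' @return `write_preprocessor` the path; `read_preprocessor` the state.
#' @export
write_preprocessor <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(medians = as.list(raw$medians), modes = as.list(raw$modes),
         caps = as.list(raw$caps),
         levels = lapply(raw$levels, as.character),
         means = as.list(raw$means), sds = as.list(raw$sds),
         standardize = isTRUE(raw$standardize)),
    class = "hfgap_preprocessor"
  )
}

#' Cohort specification
#'
#' @param n_cases,n_controls development-cohort composition (balanced by
#'   design; defaults are the study's 10 000 / 9 995).
#' @param validation_sizes sizes of the independent validation cohorts.
#' @param low_prev_n_cases,low_prev_n_controls composition of the
#'   low-prevalence evaluation set (defaults 175 / 8 541, ~2% prevalence).
#' @param split_fraction training share of the stratified development split.
#' @param seed sampling seed.
#' @return object of class `hfgap_cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 10000, n_controls = 9995,
                        validation_sizes = c(20000, 17041),
                        low_prev_n_cases = 175, low_prev_n_controls = 8541,
                        split_fraction = 0.8, seed = 1L) {
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         validation_sizes = validation_sizes,
         low_prev_n_cases = low_prev_n_cases,
         low_prev_n_controls = low_prev_n_controls,
         split_fraction = split_fraction, seed = as.integer(seed)),
    class = "hfgap_cohort_spec"
  )
}

#' Assemble development, validation, and low-prevalence cohorts
#'
#' Samples a balanced development cohort, then the validation cohorts from the
#' remaining pool, then the low-prevalence set -- all pairwise disjoint by
#' patient id. An 80/20 stratified split is drawn inside the development
#' cohort.
#'
#' @param features tibble with at least `patient_id` and `label`
#'   (`"HF"`/`"NON_HF"`).
#' @param spec an [cohort_spec()] object.
#' @return list of character id vectors: `development`, `validation` (a list,
#'   one per requested size), `low_prevalence`, plus `dev_split` (tibble
#'   `patient_id`, `partition` in train/test).
#' @export
assemble_cohorts <- function(features, spec) {
  stopifnot(inherits(spec, "hfgap_cohort_spec"))
  set.seed(spec$seed)
  cases <- features$patient_id[features$label == "HF"]
  controls <- features$patient_id[features$label == "NON_HF"]
  take <- function(pool, k, what) {
    if (length(pool) < k) {
      stop("insufficient patients in stratum ", what, ": need ", k,
           ", have ", length(pool), call. = FALSE)
    }
    sample(pool, k)
  }
  dev_cases <- take(cases, spec$n_cases, "cases (development)")
  dev_controls <- take(controls, spec$n_controls, "controls (development)")
  development <- c(dev_cases, dev_controls)

  remaining <- setdiff(features$patient_id, development)
  validation <- list()
  for (i in seq_along(spec$validation_sizes)) {
    v <- take(remaining, spec$validation_sizes[i],
              paste0("validation cohort ", i))
    validation[[i]] <- v
    remaining <- setdiff(remaining, v)
  }
  lp_cases <- take(intersect(remaining, cases), spec$low_prev_n_cases,
                   "cases (low prevalence)")
  lp_controls <- take(intersect(remaining, controls),
                      spec$low_prev_n_controls, "controls (low prevalence)")
  low_prevalence <- c(lp_cases, lp_controls)

  # stratified 80/20 split inside development
  n_tr_cases <- round(spec$split_fraction * length(dev_cases))
  n_tr_controls <- round(spec$split_fraction * length(dev_controls))
  tr <- c(sample(dev_cases, n_tr_cases), sample(dev_controls, n_tr_controls))
  dev_split <- tibble::tibble(
    patient_id = development,
    partition = ifelse(development %in% tr, "train", "test")
  )

  list(development = development, validation = validation,
       low_prevalence = low_prevalence, dev_split = dev_split)
}

#' Assert the washout leakage contract on a built cohort
#'
#' Machine check that for every HF-labelled patient the latest event used for
#' features predates the first I50 date by at least the washout, and that no
#' feature event falls after the feature window end.
#'
#' @param events the windowed events actually used for features.
#' @param index_dates tibble `patient_id`, `index_date`.
#' @param washout_days washout length.
#' @param feature_end_year last permitted event year.
#' @return `TRUE` invisibly; stops with a diagnostic on violation.
#' @export
assert_no_leakage <- function(events, index_dates, washout_days = 365,
                              feature_end_year = 2021) {
  ev <- dplyr::inner_join(events, index_dates, by = "patient_id")
  late_year <- as.integer(format(ev$event_date, "%Y")) > feature_end_year
  if (any(late_year)) {
    stop("leakage: ", sum(late_year), " event(s) after the feature window end",
         call. = FALSE)
  }
  cases <- !is.na(ev$index_date)
  bad <- cases & ev$event_date > ev$index_date - washout_days
  if (any(bad)) {
    stop("leakage: ", sum(bad), " case event(s) inside the washout window",
         call. = FALSE)
  }
  invisible(TRUE)
}
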