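test_that("completeness filter retains exactly the fully observed patients", {
  demo <- tibble::tibble(
    patient_id = sprintf("P%d", 1:5),
    age = c(60, 61, 62, 63, 64),
    sex = c("male", "female", "male", "male", "female"),
    race = c("parda", NA, "branca", "preta", "parda"),
    height = c(1.7, 1.6, 1.8, 1.7, 1.6),
    weight = c(70, 60, 80, 75, 65))
  expect_setequal(completeness_filter(demo), c("P1", "P3", "P4", "P5"))
  expect_identical(completeness_filter(demo[c(1, 3), ]),
                   c("P1", "P3"))
  demo$age <- NA
  expect_warning(out <- completeness_filter(demo), "no patient")
  expect_length(out, 0)
})

test_that("washout boundary arithmetic is inclusive at 365 days", {
  ev <- make_events(
    list("A", "2021-05-31", "I25"),   # 366 days before index: kept
    list("A", "2021-06-01", "E78"),   # exactly 365 days before: kept
    list("A", "2021-09-01", "E78"),   # 273 days before: dropped
    list("B", "2021-12-30", "Z00"),   # control, inside window: kept
    list("B", "2022-01-05", "Z00")    # control, 2022: dropped
  )
  idx <- tibble::tibble(patient_id = c("A", "B"),
                        index_date = as.Date(c("2022-06-01", NA)))
  out <- apply_washout(ev, idx)
  expect_identical(out$event_date,
                   as.Date(c("2021-05-31", "2021-06-01", "2021-12-30")))
  expect_silent(assert_no_leakage(out, idx))
  expect_error(assert_no_leakage(ev, idx), "leakage")
})

test_that("cases whose events all fall in the washout are kept and flagged", {
  ev <- make_events(list("A", "2022-01-15", "I25"))
  idx <- tibble::tibble(patient_id = "A",
                        index_date = as.Date("2022-06-01"))
  expect_message(out <- apply_washout(ev, idx), "zero events")
  expect_equal(nrow(out), 0)
  expect_identical(attr(out, "zero_event_patients"), "A")
})

test_that("feature building counts codes, chapters and procedures", {
  ev <- make_events(
    list("A", "2019-01-01", "I25"),
    list("A", "2019-02-01", "I25"),
    list("A", "2019-03-01", "I251"),
    list("A", "2019-04-01", "E78"),
    list("A", "2019-05-01", "R07", "ECHO")
  )
  demo <- tibble::tibble(patient_id = c("A", "B"), age = c(60, 50),
                         sex = c("male", "female"),
                         race = c("parda", "branca"),
                         height = c(1.7, 1.6), weight = c(70, 60),
                         bmi = c(24.2, 23.4))
  feats <- build_features(ev, demo)
  a <- feats[feats$patient_id == "A", ]
  b <- feats[feats$patient_id == "B", ]
  expect_equal(a$code_I25, 3)
  expect_equal(a$code_E78, 1)
  expect_equal(a$chapter_IX, 3)
  expect_equal(a$chapter_IV, 1)
  expect_equal(a$proc_ECHO, 1)
  # patient with zero events gets all-zero counts
  expect_equal(b$code_I25, 0)
  expect_equal(b$chapter_IX, 0)
})

test_that("plausibility filter drops implausible ages/BMI, caps counts", {
  train <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:100), age = rep(60, 100),
    bmi = rep(25, 100), code_I25 = c(rep(1, 99), 500))
  state <- fit_preprocessor(train)
  dat <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    age = c(17, 60, 60, 60),
    bmi = c(25, 61, 25, 25),
    code_I25 = c(1, 1, 1, 400))
  out <- plausibility_filter(dat, state)
  expect_setequal(out$patient_id, c("c", "d"))
  expect_true(is.na(out$code_I25[out$patient_id == "d"]))
  # after imputation the capped value is replaced by the training median
  applied <- apply_preprocessor(state, out)
  expect_equal(applied$x[applied$patient_id == "d", "code_I25"][[1]], 1)
})

test_that("preprocessor imputes from training statistics only", {
  train <- tibble::tibble(patient_id = c("t1", "t2", "t3"),
                          bmi = c(24, 26, 28),
                          sex = c("male", "male", "female"))
  state <- fit_preprocessor(train)
  apply_to <- tibble::tibble(patient_id = "x", bmi = NA_real_,
                             sex = NA_character_)
  out <- apply_preprocessor(state, apply_to)
  expect_equal(out$x[1, "bmi"][[1]], 26)        # training median
  expect_equal(out$x[1, "sex_male"][[1]], 1)    # training mode
  # one-hot indicators sum to 1 per row
  expect_equal(out$x[1, "sex_female"] + out$x[1, "sex_male"], 1,
               ignore_attr = TRUE)
  # applying the same state to different data never changes the statistics
  other <- tibble::tibble(patient_id = "y", bmi = 1000, sex = "female")
  expect_equal(apply_preprocessor(state, apply_to)$x, out$x)
})

test_that("preprocessor state round-trips through JSON", {
  pop <- generate_population(generator_config(n_patients = 300, seed = 6))
  feats <- build_features(pop$events, pop$demographics)
  state <- fit_preprocessor(feats, standardize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocessor(state, path)
  state2 <- read_preprocessor(path)
  expect_equal(apply_preprocessor(state2, feats)$x,
               apply_preprocessor(state, feats)$x)
})

test_that("cohort assembly yields the requested disjoint strata", {
  set.seed(99)
  feats <- tibble::tibble(
    patient_id = sprintf("P%05d", 1:5000),
    label = ifelse(runif(5000) < 0.3, "HF", "NON_HF"))
  spec <- cohort_spec(n_cases = 400, n_controls = 395,
                      validation_sizes = c(800, 600),
                      low_prev_n_cases = 10, low_prev_n_controls = 490,
                      seed = 3)
  coh <- assemble_cohorts(feats, spec)
  expect_length(coh$development, 795)
  expect_length(coh$validation[[1]], 800)
  expect_length(coh$validation[[2]], 600)
  expect_length(coh$low_prevalence, 500)
  sets <- c(list(coh$development), coh$validation, list(coh$low_prevalence))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) expect_length(intersect(sets[[i]], sets[[j]]), 0)
  }
  # split is stratified within one count per label
  lab <- feats$label[match(coh$dev_split$patient_id, feats$patient_id)]
  tr <- coh$dev_split$partition == "train"
  expect_equal(sum(tr & lab == "HF"), round(0.8 * 400))
  expect_equal(sum(tr & lab == "NON_HF"), round(0.8 * 395))
  # insufficient stratum errors name the stratum
  expect_error(
    assemble_cohorts(feats, cohort_spec(n_cases = 4000, n_controls = 10,
                                        validation_sizes = 10,
                                        low_prev_n_cases = 1,
                                        low_prev_n_controls = 1)),
    "cases \\(development\\)")
})
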