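test_that("ambulatory flowchart follows the trigger conjunction rule", {
  ev <- make_events(
    list("A", "2019-03-01", "I25"),
    list("A", "2019-04-02", "Z00", "ECHO"),
    list("B", "2020-01-01", "I500"),
    list("C", "2019-03-01", "I25")
  )
  out <- classify_ambulatory(ev, trigger_icds, trigger_procs)
  out <- out[match(c("A", "B", "C"), out$patient_id), ]
  expect_identical(out$label, c("POTENTIAL_HF", "DIAGNOSED_HF", "NEITHER"))
  expect_identical(out$first_i50_date[2], as.Date("2020-01-01"))
  expect_identical(out$classification_year, c(2019L, 2020L, NA_integer_))
  expect_identical(out$trigger_icds_hit[1], "I25")
  expect_identical(out$trigger_procedures_hit[1], "ECHO")
})

test_that("trigger_logic = 'or' accepts either trigger condition", {
  ev <- make_events(list("C", "2019-03-01", "I25"))
  out <- classify_ambulatory(ev, trigger_icds, trigger_procs,
                             trigger_logic = "or")
  expect_identical(out$label, "POTENTIAL_HF")
})

test_that("patients with no events are NEITHER, with a note", {
  ev <- make_events(list("A", "2019-03-01", "I25"))
  expect_message(
    out <- classify_ambulatory(ev, trigger_icds, trigger_procs,
                               patient_ids = c("A", "B")),
    "no events")
  expect_identical(out$label[out$patient_id == "B"], "NEITHER")
})

test_that("classification matches brute-force enumeration on random patients", {
  set.seed(31)
  icd_pool <- c("I50", "I500", "I21", "I25", "I42", "I48", "E78", "Z00", "J44")
  proc_pool <- c(NA, NA, "ECHO", "BNP", "ECG", "OTHER")
  ev <- tibble::tibble(
    patient_id = sample(sprintf("P%03d", 1:150), 600, replace = TRUE),
    event_date = as.Date("2018-01-01") + sample(0:1500, 600, replace = TRUE),
    icd10 = sample(icd_pool, 600, replace = TRUE),
    procedure = sample(proc_pool, 600, replace = TRUE)
  )
  got <- classify_ambulatory(ev, trigger_icds, trigger_procs)
  oracle <- vapply(got$patient_id, function(pid) {
    sub <- ev[ev$patient_id == pid, ]
    has_i50 <- any(substr(sub$icd10, 1, 3) == "I50")
    has_ti <- any(substr(sub$icd10, 1, 3) %in% c("I21", "I25", "I42", "I48"))
    has_tp <- any(!is.na(sub$procedure) &
                    sub$procedure %in% c("ECHO", "BNP", "CATH", "ERGO",
                                         "CHAGAS_SERO"))
    if (has_i50) "DIAGNOSED_HF"
    else if (has_ti && has_tp) "POTENTIAL_HF"
    else "NEITHER"
  }, character(1))
  expect_identical(got$label, unname(oracle))
  # exhaustive partition: one label per patient
  expect_identical(sort(unique(ev$patient_id)), sort(got$patient_id))
})

test_that("adding an I50 event only ever moves a patient to DIAGNOSED_HF", {
  ev <- make_events(
    list("A", "2019-03-01", "I25"),
    list("A", "2019-04-02", "Z00", "ECHO"),
    list("B", "2019-05-01", "E78")
  )
  before <- classify_ambulatory(ev, trigger_icds, trigger_procs)
  for (pid in c("A", "B")) {
    ev2 <- dplyr::bind_rows(ev, make_events(list(pid, "2021-01-01", "I509")))
    after <- classify_ambulatory(ev2, trigger_icds, trigger_procs)
    expect_identical(after$label[after$patient_id == pid], "DIAGNOSED_HF")
    other <- setdiff(c("A", "B"), pid)
    expect_identical(after$label[after$patient_id == other],
                     before$label[before$patient_id == other])
  }
})

test_that("death certificates classify by I50 location and mortality set", {
  certs <- dplyr::bind_rows(
    make_death("D1", underlying = "I500"),
    make_death("D2", underlying = "R99", line_a = "I21"),
    make_death("D3", underlying = "I21"),
    make_death("D4", underlying = "R99", part2 = "I42"),
    make_death("D5", underlying = "I21", line_b = "I500")
  )
  out <- classify_death(certs, mortality_set)
  expect_identical(out$label,
                   c("HF_DEATH", "POTENTIAL_HF_DEATH", "OTHER",
                     "POTENTIAL_HF_DEATH", "HF_DEATH"))
  expect_identical(out$subclass,
                   c("NONE", "ISCHAEMIC", "NONE", "CARDIOMYOPATHY", "NONE"))
  expect_identical(out$matched_codes[2], "I21")
})

test_that("cause subclassification follows the ischaemic-first priority", {
  expect_identical(subclassify_cause("I21"), "ISCHAEMIC")
  expect_identical(subclassify_cause("I42"), "CARDIOMYOPATHY")
  expect_identical(subclassify_cause(c("I21", "I42")), "ISCHAEMIC")
  expect_identical(subclassify_cause(c("I35", "I42")), "VALVULAR")
  expect_identical(subclassify_cause("B57"), "CARDIOMYOPATHY")
  expect_identical(subclassify_cause("I48"), "OTHER_CARDIAC")
  expect_identical(subclassify_cause(character(0)), "NONE")
})

test_that("yearly summaries compute per-row means and percentages", {
  pheno <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    label = c("DIAGNOSED_HF", "DIAGNOSED_HF", "POTENTIAL_HF", "POTENTIAL_HF"),
    classification_year = 2018L
  )
  demo <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    age = c(50, 60, 70, 80),
    sex = c("male", "female", "male", "male")
  )
  out <- summarize_by_year(pheno, demo)
  expect_equal(out$mean_age[out$label == "DIAGNOSED_HF"], 55)
  expect_equal(out$mean_age[out$label == "POTENTIAL_HF"], 75)
  expect_equal(out$pct_male[out$label == "POTENTIAL_HF"], 100)
  expect_equal(nrow(out), 2) # empty years omitted
})

test_that("the printed-table male percentage is reproduced", {
  tab <- summarize_counts_table(reported_yearly_counts())
  row <- tab[tab$stream == "ambulatory" & tab$label == "diagnosed" &
               tab$year == 2018, ]
  expect_equal(row$pct_male, 45.19)
})

test_that("proxy/model concordance matches the printed overlap", {
  proxy <- sprintf("x%06d", 1:76757)
  model <- c(proxy[1:71242], sprintf("y%06d", 1:5000))
  out <- proxy_model_concordance(proxy, model)
  expect_equal(out$overlap, 71242)
  expect_equal(out$percentage, 92.81)
  expect_equal(proxy_model_concordance(proxy, proxy)$percentage, 100)
  expect_equal(proxy_model_concordance(proxy, "zzz")$percentage, 0)
  expect_error(proxy_model_concordance(character(0), proxy), "empty proxy")
})

test_that("masked synthetic HF deaths are recovered as potential deaths", {
  cfg <- generator_config(n_patients = 8000, true_hf_prevalence = 0.3,
                          annual_death_rate = 0.04,
                          hf_death_masking_probability = 0.5, seed = 17)
  pop <- generate_population(cfg)
  out <- classify_death(pop$deaths, mortality_set)
  j <- dplyr::inner_join(out, pop$truth, by = c("person_id" = "patient_id"))
  hf_deaths <- j[j$true_hf_death, ]
  phat <- mean(hf_deaths$label == "POTENTIAL_HF_DEATH")
  expect_lt(abs(phat - 0.5),
            2.576 * sqrt(0.5 * 0.5 / nrow(hf_deaths)))
  # unmasked HF deaths all carry I50
  expect_true(all(hf_deaths$label %in% c("HF_DEATH", "POTENTIAL_HF_DEATH")))
})
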