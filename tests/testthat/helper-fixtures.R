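# in-code fixtures shared across test files

make_events <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), 1),
    event_date = as.Date(vapply(rows, `[[`, character(1), 2)),
    icd10 = vapply(rows, `[[`, character(1), 3),
    procedure = vapply(rows, function(r) {
      if (length(r) >= 4) r[[4]] else NA_character_
    }, character(1))
  )
}

make_death <- function(person_id = "D1", underlying = "R99",
                       line_a = NA, line_b = NA, line_c = NA, line_d = NA,
                       part2 = NA, death_date = "2020-06-01",
                       age = 70, sex = "male") {
  tibble::tibble(
    person_id = person_id, death_date = as.Date(death_date),
    age_at_death = age, sex = sex, underlying_cause = underlying,
    line_a = as.character(line_a), line_b = as.character(line_b),
    line_c = as.character(line_c), line_d = as.character(line_d),
    part2 = as.character(part2)
  )
}

trigger_icds <- hfgap::default_codesets()$ambulatory_icds
trigger_procs <- hfgap::default_codesets()$ambulatory_procedures
mortality_set <- hfgap::default_codesets()$mortality

# brute-force AUC oracle: pairwise concordance with half credit for ties
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# signal-bearing generator config used by modelling tests
signal_config <- function(n, seed, timing = "pre", prevalence = 0.3) {
  plant_feature_signal(
    generator_config(n_patients = n, true_hf_prevalence = prevalence,
                     coding_probability = 1, seed = seed,
                     signal_timing = timing),
    c(N18 = 2.0, ECHO = 2.5, I25 = 2.0, E78 = 1.0)
  )
}

# small balanced feature table with one informative and one noise feature
toy_features <- function(n = 200, beta = 3, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  p <- stats::plogis(beta * x)
  lab <- ifelse(stats::runif(n) < p, "HF", "NON_HF")
  tibble::tibble(
    patient_id = sprintf("T%04d", seq_len(n)),
    label = lab, signal = x, noise = noise
  )
}
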