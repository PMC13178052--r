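# Synthetic claims generator with known latent truth.
#
# Every patient-level condition or procedure is decomposed into a *baseline*
# component (identical stochastic process for HF and non-HF patients, events
# spread over the whole extraction window) and an *excess* component carried
# only by true-HF patients. The excess presence probability is chosen so the
# marginal presence probability among true HF equals the configured odds-ratio
# shift exactly, which makes planted effects recoverable in closed form.
# `signal_timing` controls where the excess events fall relative to the first
# I50 code: spread over the pre-diagnostic history (`"pre"`, default) or
# confined to the 12 months immediately before it (`"washout_only"`, used to
# probe leakage through the washout boundary).

default_comorbidity_rates <- function() {
  list(
    I21 = list(base = 0.020, hf_or = 6.0),  # acute myocardial infarction
    I25 = list(base = 0.050, hf_or = 6.0),  # chronic ischaemic heart disease
    I42 = list(base = 0.010, hf_or = 8.0),  # cardiomyopathy
    I48 = list(base = 0.030, hf_or = 5.0),  # atrial fibrillation / flutter
    N18 = list(base = 0.040, hf_or = 4.0),  # chronic kidney disease
    E78 = list(base = 0.100, hf_or = 2.5),  # lipoprotein metabolism disorders
    E11 = list(base = 0.100, hf_or = 2.0),  # type 2 diabetes
    I10 = list(base = 0.200, hf_or = 2.5),  # essential hypertension
    J44 = list(base = 0.050, hf_or = 1.8),  # COPD
    B57 = list(base = 0.005, hf_or = 5.0)   # Chagas disease
  )
}

default_procedure_rates <- function() {
  list(
    ECHO        = list(base = 0.050, hf_or = 8.0, per_year = 0.8),
    BNP         = list(base = 0.010, hf_or = 10.0, per_year = 0.8),
    CATH        = list(base = 0.005, hf_or = 8.0, per_year = 0.4),
    ERGO        = list(base = 0.005, hf_or = 6.0, per_year = 0.4),
    CHAGAS_SERO = list(base = 0.005, hf_or = 5.0, per_year = 0.4),
    ECG         = list(base = 0.150, hf_or = 3.0, per_year = 0.8),
    ABPM        = list(base = 0.030, hf_or = 2.0, per_year = 0.4)
  )
}

default_demographics_spec <- function() {
  list(
    age_mean = 61, age_sd = 14.5, age_range = c(18, 100),
    p_male = 0.54,
    race_levels = c("branca", "parda", "preta", "amarela", "indigena"),
    race_probs = c(0.45, 0.40, 0.10, 0.04, 0.01),
    height_mean = c(male = 1.72, female = 1.60), height_sd = 0.08,
    weight_mean = c(male = 78, female = 68), weight_sd = 14
  )
}

#' Configuration for the synthetic claims generator
#'
#' Defaults describe a population shaped like the study setting: 2018--2022
#' study window with a 3-year lookback, mean age about 61 (SD 14.5), ~54% male,
#' comorbidity and investigation-procedure prevalences elevated among true-HF
#' patients, and death certification that can mask HF deaths under
#' ischaemic/cardiomyopathy codes.
#'
#' @param n_patients number of patients to simulate.
#' @param study_years inclusive year range of the study window.
#' @param lookback_years extra years of extraction before the study window.
#' @param true_hf_prevalence fraction of patients with latent true HF.
#' @param coding_probability probability that a true-HF patient ever receives
#'   an I50 code inside the extraction window.
#' @param comorbidity_rates named list `prefix -> list(base, hf_or)`: baseline
#'   presence probability and odds ratio among true HF.
#' @param procedure_rates named list `proc -> list(base, hf_or, per_year)`.
#' @param baseline_event_rate per-patient-per-year Poisson rate of background
#'   (non-informative) billed events.
#' @param comorbidity_event_rate per-year event rate for a present condition.
#' @param annual_death_rate annual death probability among non-HF patients.
#' @param hf_death_rate_multiplier multiplier on the annual death rate for
#'   true-HF patients.
#' @param true_hf_death_probability probability that the death of a true-HF
#'   patient is an HF death.
#' @param hf_death_masking_probability probability that a true-HF death is
#'   certified under an ischaemic/cardiomyopathy code with no I50 anywhere.
#' @param nonhf_trigger_death_rate probability that a non-HF death still
#'   carries a mortality-set code on the certificate lines (e.g. fatal
#'   myocardial infarction without HF).
#' @param demographics_spec list of demographic means/SDs and category
#'   probabilities; see `default_demographics_spec()` in the source.
#' @param missingness_rates named completely-at-random missingness fractions
#'   for demographic fields.
#' @param signal_timing `"pre"` or `"washout_only"` (see file header).
#' @param seed integer seed; identical configs give byte-identical output.
#' @return an object of class `hfgap_generator_config`.
#' @export
generator_config <- function(n_patients,
                             study_years = c(2018, 2022),
                             lookback_years = 3,
                             true_hf_prevalence = 0.08,
                             coding_probability = 0.7,
                             comorbidity_rates = default_comorbidity_rates(),
                             procedure_rates = default_procedure_rates(),
                             baseline_event_rate = 1.0,
                             comorbidity_event_rate = 0.4,
                             annual_death_rate = 0.012,
                             hf_death_rate_multiplier = 4,
                             true_hf_death_probability = 0.7,
                             hf_death_masking_probability = 0.5,
                             nonhf_trigger_death_rate = 0.15,
                             demographics_spec = default_demographics_spec(),
                             missingness_rates = c(race = 0.03, height = 0.04,
                                                   weight = 0.04),
                             signal_timing = c("pre", "washout_only"),
                             seed = 1L) {
  signal_timing <- match.arg(signal_timing)
  fracs <- c(true_hf_prevalence, coding_probability,
             hf_death_masking_probability, true_hf_death_probability,
             nonhf_trigger_death_rate, annual_death_rate, missingness_rates)
  stopifnot(n_patients >= 1, lookback_years >= 0,
            all(fracs >= 0 & fracs <= 1))
  structure(
    list(n_patients = as.integer(n_patients),
         study_years = as.integer(study_years),
         lookback_years = as.integer(lookback_years),
         true_hf_prevalence = true_hf_prevalence,
         coding_probability = coding_probability,
         comorbidity_rates = comorbidity_rates,
         procedure_rates = procedure_rates,
         baseline_event_rate = baseline_event_rate,
         comorbidity_event_rate = comorbidity_event_rate,
         annual_death_rate = annual_death_rate,
         hf_death_rate_multiplier = hf_death_rate_multiplier,
         true_hf_death_probability = true_hf_death_probability,
         hf_death_masking_probability = hf_death_masking_probability,
         nonhf_trigger_death_rate = nonhf_trigger_death_rate,
         demographics_spec = demographics_spec,
         missingness_rates = missingness_rates,
         signal_timing = signal_timing,
         seed = as.integer(seed)),
    class = "hfgap_generator_config"
  )
}

#' Plant a known feature signal into a generator configuration
#'
#' Resets every comorbidity and procedure odds ratio to 1 (no signal), then
#' applies the requested conditional log-odds shifts, so the returned config
#' carries signal exactly where specified. A shift `b` on feature `f` makes
#' the odds ratio of `f`-presence between true-HF and non-HF patients equal
#' `exp(b)` by construction.
#'
#' @param config an [generator_config()] object.
#' @param effect_sizes named numeric vector: feature (comorbidity prefix or
#'   procedure id) -> log-odds shift.
#' @return modified config.
#' @export
plant_feature_signal <- function(config, effect_sizes = numeric(0)) {
  stopifnot(inherits(config, "hfgap_generator_config"))
  known <- c(names(config$comorbidity_rates), names(config$procedure_rates))
  unknown <- setdiff(names(effect_sizes), known)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(config$comorbidity_rates)) {
    config$comorbidity_rates[[nm]]$hf_or <- 1
  }
  for (nm in names(config$procedure_rates)) {
    config$procedure_rates[[nm]]$hf_or <- 1
  }
  for (nm in names(effect_sizes)) {
    or <- exp(effect_sizes[[nm]])
    if (nm %in% names(config$comorbidity_rates)) {
      config$comorbidity_rates[[nm]]$hf_or <- or
    } else {
      config$procedure_rates[[nm]]$hf_or <- or
    }
  }
  config
}

# Marginal presence among true HF implied by (base, or): logit-shift model.
presence_among_hf <- function(base, or) {
  stats::plogis(stats::qlogis(base) + log(or))
}

# Excess presence probability so base + excess components compose to p_hf.
excess_probability <- function(base, or) {
  p_hf <- presence_among_hf(base, or)
  pmax(0, (p_hf - base) / (1 - base))
}

runif_dates <- function(n, start, end) {
  span <- as.numeric(end - start)
  start + floor(stats::runif(n) * (span + 1))
}

background_icd_pool <- function() {
  c("E66", "M54", "K21", "Z00", "R51", "J06", "A09", "L23", "H52", "F41",
    "G43", "K02", "N39", "R10", "D64", "J30", "M17", "E03", "K29", "R05")
}

procedure_justification_pool <- function() {
  c("R07", "R06", "Z03", "R00", "Z01")
}

masked_cause_pool <- function() {
  # heavily ischaemic, matching the observed predominance of infarction and
  # ischaemia among potential HF deaths (~98%)
  c(I21 = 0.590, I25 = 0.390, I42 = 0.008, I35 = 0.004, I48 = 0.004,
    I05 = 0.002, I49 = 0.001, I51 = 0.001)
}

noncardiac_cause_pool <- function() {
  c("C34", "J18", "A41", "E14", "C16", "J44", "G30", "N18", "C61", "E86")
}

#' Generate a synthetic claims population with latent truth
#'
#' Produces the four tables consumed by the downstream stages: ambulatory
#' events, death certificates, demographics, and the latent-truth table that
#' records each patient's true HF status, onset and coding dates, and death
#' classification. Fully reproducible from `config$seed`.
#'
#' @param config an [generator_config()] object.
#' @return named list of tibbles: `events`, `deaths`, `demographics`, `truth`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "hfgap_generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  win_start <- as.Date(sprintf("%d-01-01",
                               config$study_years[1] - config$lookback_years))
  study_start <- as.Date(sprintf("%d-01-01", config$study_years[1]))
  win_end <- as.Date(sprintf("%d-12-31", config$study_years[2]))
  n_years <- config$study_years[2] - config$study_years[1] + 1 +
    config$lookback_years

  ids <- sprintf("P%07d", seq_len(n))

  ## latent truth -----------------------------------------------------------
  true_hf <- stats::runif(n) < config$true_hf_prevalence
  if (sum(true_hf) < 1) {
    warning("expected true-HF count below 1; population may contain no cases",
            call. = FALSE)
  }
  onset <- runif_dates(n, study_start, win_end)
  onset[!true_hf] <- NA
  coded <- true_hf & (stats::runif(n) < config$coding_probability)
  delay <- floor(stats::runif(n) * 731)  # 0-24 months in days
  first_i50 <- pmin(onset + delay, win_end)
  first_i50[!coded] <- NA

  ## demographics ------------------------------------------------------------
  ds <- config$demographics_spec
  age <- pmin(pmax(stats::rnorm(n, ds$age_mean, ds$age_sd),
                   ds$age_range[1]), ds$age_range[2])
  sex <- ifelse(stats::runif(n) < ds$p_male, "male", "female")
  race <- sample(ds$race_levels, n, replace = TRUE, prob = ds$race_probs)
  height <- stats::rnorm(n, ds$height_mean[ifelse(sex == "male", "male",
                                                  "female")], ds$height_sd)
  weight <- stats::rnorm(n, ds$weight_mean[ifelse(sex == "male", "male",
                                                  "female")], ds$weight_sd)
  height <- pmax(height, 1.2)
  weight <- pmax(weight, 30)
  demographics <- tibble::tibble(
    patient_id = ids, age = round(age, 1), sex = sex, race = race,
    height = round(height, 2), weight = round(weight, 1)
  )
  for (fld in names(config$missingness_rates)) {
    miss <- stats::runif(n) < config$missingness_rates[[fld]]
    demographics[[fld]][miss] <- NA
  }
  demographics$bmi <- round(demographics$weight / demographics$height^2, 2)

  ## event generation --------------------------------------------------------
  # timing anchor for excess events
  anchor <- first_i50
  anchor[is.na(anchor)] <- onset[is.na(anchor)]

  event_parts <- list()

  emit_events <- function(idx, lambda, icd_fun, proc, start_vec, end_vec) {
    # idx: patient indices; one block of events with per-patient Poisson counts
    counts <- 1L + stats::rpois(length(idx), lambda)
    rows <- rep(seq_along(idx), counts)
    m <- length(rows)
    if (m == 0) return(NULL)
    starts <- start_vec[rows]
    ends <- end_vec[rows]
    tibble::tibble(
      patient_id = ids[idx][rows],
      event_date = pmin(pmax(runif_dates(m, starts, ends), win_start), win_end),
      icd10 = icd_fun(m),
      procedure = proc
    )
  }

  # background events: identical non-informative process for everyone
  bg_counts <- stats::rpois(n, config$baseline_event_rate * n_years)
  bg_rows <- rep(seq_len(n), bg_counts)
  if (length(bg_rows)) {
    event_parts$background <- tibble::tibble(
      patient_id = ids[bg_rows],
      event_date = runif_dates(length(bg_rows), win_start, win_end),
      icd10 = sample(background_icd_pool(), length(bg_rows), replace = TRUE),
      procedure = NA_character_
    )
  }

  span_years <- n_years
  full_start <- rep(win_start, n)
  full_end <- rep(win_end, n)
  # excess window per patient by signal timing
  if (config$signal_timing == "washout_only") {
    ex_start <- pmax(anchor - 365, win_start)
    ex_end <- pmax(anchor - 1, win_start)
  } else {
    ex_start <- rep(win_start, n)
    ex_end <- pmin(anchor, win_end)
  }
  ex_end[is.na(ex_end)] <- win_end
  ex_start[is.na(ex_start)] <- win_start

  for (nm in names(config$comorbidity_rates)) {
    cr <- config$comorbidity_rates[[nm]]
    present_base <- stats::runif(n) < cr$base
    p_ex <- excess_probability(cr$base, cr$hf_or)
    present_ex <- true_hf & (stats::runif(n) < p_ex)
    lam <- config$comorbidity_event_rate * span_years
    idx_b <- which(present_base)
    if (length(idx_b)) {
      event_parts[[paste0("c_b_", nm)]] <- emit_events(
        idx_b, lam, function(m) rep(nm, m), NA_character_,
        full_start[idx_b], full_end[idx_b])
    }
    idx_e <- which(present_ex)
    if (length(idx_e)) {
      event_parts[[paste0("c_e_", nm)]] <- emit_events(
        idx_e, config$comorbidity_event_rate * 2, function(m) rep(nm, m),
        NA_character_, ex_start[idx_e], ex_end[idx_e])
    }
  }

  just_pool <- procedure_justification_pool()
  for (nm in names(config$procedure_rates)) {
    pr <- config$procedure_rates[[nm]]
    user_base <- stats::runif(n) < pr$base
    p_ex <- excess_probability(pr$base, pr$hf_or)
    user_ex <- true_hf & (stats::runif(n) < p_ex)
    lam <- pr$per_year * span_years * 0.3
    idx_b <- which(user_base)
    if (length(idx_b)) {
      event_parts[[paste0("p_b_", nm)]] <- emit_events(
        idx_b, lam, function(m) sample(just_pool, m, replace = TRUE), nm,
        full_start[idx_b], full_end[idx_b])
    }
    idx_e <- which(user_ex)
    if (length(idx_e)) {
      event_parts[[paste0("p_e_", nm)]] <- emit_events(
        idx_e, pr$per_year, function(m) sample(just_pool, m, replace = TRUE),
        nm, ex_start[idx_e], ex_end[idx_e])
    }
  }

  # I50 events for coded patients: first at first_i50_date, extras after
  idx_c <- which(coded)
  if (length(idx_c)) {
    i50_codes <- c("I50", "I500", "I501", "I509")
    extras <- stats::rpois(length(idx_c), 0.8)
    first_rows <- tibble::tibble(
      patient_id = ids[idx_c],
      event_date = first_i50[idx_c],
      icd10 = sample(i50_codes, length(idx_c), replace = TRUE),
      procedure = NA_character_
    )
    er <- rep(seq_along(idx_c), extras)
    extra_rows <- NULL
    if (length(er)) {
      extra_rows <- tibble::tibble(
        patient_id = ids[idx_c][er],
        event_date = runif_dates(length(er), first_i50[idx_c][er],
                                 rep(win_end, length(er))),
        icd10 = sample(i50_codes, length(er), replace = TRUE),
        procedure = NA_character_
      )
    }
    event_parts$i50 <- dplyr::bind_rows(first_rows, extra_rows)
  }

  events <- dplyr::bind_rows(event_parts)
  events <- dplyr::arrange(events, .data$patient_id, .data$event_date,
                           .data$icd10)

  ## deaths -------------------------------------------------------------------
  annual <- ifelse(true_hf,
                   pmin(1, config$annual_death_rate *
                          config$hf_death_rate_multiplier),
                   config$annual_death_rate)
  study_span <- config$study_years[2] - config$study_years[1] + 1
  p_die <- 1 - (1 - annual)^study_span
  died <- stats::runif(n) < p_die
  death_date <- runif_dates(n, study_start, win_end)
  # HF deaths cannot precede onset
  fix <- died & true_hf & !is.na(onset) & death_date < onset
  death_date[fix] <- pmin(onset[fix] + floor(stats::runif(sum(fix)) * 365),
                          win_end)
  true_hf_death <- died & true_hf &
    (stats::runif(n) < config$true_hf_death_probability)

  idx_d <- which(died)
  n_d <- length(idx_d)
  deaths <- NULL
  if (n_d) {
    masked <- true_hf_death[idx_d] &
      (stats::runif(n_d) < config$hf_death_masking_probability)
    hf_open <- true_hf_death[idx_d] & !masked
    other <- !true_hf_death[idx_d]
    other_trigger <- other & (stats::runif(n_d) < config$nonhf_trigger_death_rate)

    mp <- masked_cause_pool()
    underlying <- character(n_d)
    line_a <- rep(NA_character_, n_d)
    line_b <- rep(NA_character_, n_d)
    part2 <- rep(NA_character_, n_d)

    # unmasked HF deaths: I50 in the underlying cause or on line A
    if (any(hf_open)) {
      k <- sum(hf_open)
      i50 <- sample(c("I500", "I509", "I50"), k, replace = TRUE)
      via_underlying <- stats::runif(k) < 0.6
      alt <- sample(names(mp), k, replace = TRUE, prob = mp)
      underlying[hf_open] <- ifelse(via_underlying, i50, alt)
      line_a[hf_open] <- ifelse(via_underlying, alt, i50)
    }
    # masked HF deaths: mortality-set code on line A, no I50 anywhere
    if (any(masked)) {
      k <- sum(masked)
      cause <- sample(names(mp), k, replace = TRUE, prob = mp)
      underlying[masked] <- cause
      line_a[masked] <- cause
      add_b <- stats::runif(k) < 0.3
      line_b[masked][add_b] <- sample(c("I10", "E11", "N18"), sum(add_b),
                                      replace = TRUE)
    }
    # non-HF deaths
    if (any(other)) {
      k <- sum(other)
      underlying[other] <- sample(noncardiac_cause_pool(), k, replace = TRUE)
    }
    if (any(other_trigger)) {
      k <- sum(other_trigger)
      line_a[other_trigger] <- sample(names(mp), k, replace = TRUE, prob = mp)
    }
    add_p2 <- stats::runif(n_d) < 0.2
    part2[add_p2] <- sample(c("E11", "I10", "J44", "F03"), sum(add_p2),
                            replace = TRUE)

    deaths <- tibble::tibble(
      person_id = ids[idx_d],
      death_date = death_date[idx_d],
      age_at_death = demographics$age[idx_d],
      sex = demographics$sex[idx_d],
      underlying_cause = underlying,
      line_a = line_a,
      line_b = line_b,
      line_c = NA_character_,
      line_d = NA_character_,
      part2 = part2
    )
  } else {
    deaths <- tibble::tibble(
      person_id = character(0), death_date = as.Date(character(0)),
      age_at_death = numeric(0), sex = character(0),
      underlying_cause = character(0), line_a = character(0),
      line_b = character(0), line_c = character(0), line_d = character(0),
      part2 = character(0)
    )
  }

  truth <- tibble::tibble(
    patient_id = ids,
    true_hf = true_hf,
    hf_onset_date = onset,
    first_i50_date = first_i50,
    died = died,
    true_hf_death = true_hf_death
  )

  list(events = events, deaths = deaths, demographics = demographics,
       truth = truth)
}
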