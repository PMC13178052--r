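# Flowchart phenotyping: ambulatory patients are DIAGNOSED_HF when any I50
# event exists, POTENTIAL_HF when (no I50) AND (>=1 trigger ICD) AND (>=1
# trigger procedure), else NEITHER. Deaths are HF_DEATH when I50 appears in
# the underlying cause or any certificate line, POTENTIAL_HF_DEATH when no
# I50 appears anywhere but a mortality-set code is present on Part I lines
# A-D or Part II (the underlying cause is excluded from that search).

#' Classify ambulatory patients by flowchart
#'
#' @param events tibble of ambulatory events (`patient_id`, `event_date`,
#'   `icd10`, `procedure`); codes must be normalized.
#' @param trigger_icds [codeset()] of trigger diagnoses.
#' @param trigger_procs [codeset()] of trigger procedures.
#' @param trigger_logic `"and"` (default; both a trigger ICD and a trigger
#'   procedure are required for POTENTIAL_HF) or `"or"`.
#' @param patient_ids optional character vector of all patients under study;
#'   patients without any event are classified NEITHER.
#' @return tibble with one row per patient: `patient_id`, `label`
#'   (`DIAGNOSED_HF` / `POTENTIAL_HF` / `NEITHER`), `classification_year`,
#'   `first_i50_date`, `trigger_icds_hit`, `trigger_procedures_hit` (the last
#'   two as comma-separated strings).
#' @export
classify_ambulatory <- function(events, trigger_icds, trigger_procs,
                                trigger_logic = c("and", "or"),
                                patient_ids = NULL) {
  trigger_logic <- match.arg(trigger_logic)
  ev <- dplyr::mutate(
    events,
    is_i50 = substr(.data$icd10, 1, 3) == "I50",
    is_trig_icd = icd_matches(.data$icd10, trigger_icds),
    is_trig_proc = !is.na(.data$procedure) &
      toupper(.data$procedure) %in% trigger_procs$procedures
  )

  per_patient <- ev |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_i50_date = if (any(.data$is_i50))
        min(.data$event_date[.data$is_i50]) else as.Date(NA),
      first_trig_icd = if (any(.data$is_trig_icd))
        min(.data$event_date[.data$is_trig_icd]) else as.Date(NA),
      first_trig_proc = if (any(.data$is_trig_proc))
        min(.data$event_date[.data$is_trig_proc]) else as.Date(NA),
      trigger_icds_hit = paste(
        sort(unique(substr(.data$icd10[.data$is_trig_icd], 1, 3))),
        collapse = ","),
      trigger_procedures_hit = paste(
        sort(unique(toupper(.data$procedure[.data$is_trig_proc]))),
        collapse = ","),
      .groups = "drop"
    )

  out <- per_patient |>
    dplyr::mutate(
      has_i50 = !is.na(.data$first_i50_date),
      has_trig = if (trigger_logic == "and") {
        !is.na(.data$first_trig_icd) & !is.na(.data$first_trig_proc)
      } else {
        !is.na(.data$first_trig_icd) | !is.na(.data$first_trig_proc)
      },
      label = dplyr::case_when(
        .data$has_i50 ~ "DIAGNOSED_HF",
        .data$has_trig ~ "POTENTIAL_HF",
        TRUE ~ "NEITHER"
      ),
      # year of the earliest qualifying event: first I50 for diagnosed, first
      # date at which the trigger rule is satisfied for potential
      qualifying_date = dplyr::case_when(
        .data$has_i50 ~ .data$first_i50_date,
        .data$has_trig & trigger_logic == "and" ~
          pmax(.data$first_trig_icd, .data$first_trig_proc),
        .data$has_trig ~ pmin(.data$first_trig_icd, .data$first_trig_proc,
                              na.rm = TRUE),
        TRUE ~ as.Date(NA)
      ),
      classification_year = as.integer(format(.data$qualifying_date, "%Y"))
    ) |>
    dplyr::select("patient_id", "label", "classification_year",
                  "first_i50_date", "trigger_icds_hit",
                  "trigger_procedures_hit")

  if (!is.null(patient_ids)) {
    absent <- setdiff(patient_ids, out$patient_id)
    if (length(absent)) {
      message(length(absent), " patient(s) had no events; classified NEITHER")
      out <- dplyr::bind_rows(out, tibble::tibble(
        patient_id = absent, label = "NEITHER",
        classification_year = NA_integer_,
        first_i50_date = as.Date(NA),
        trigger_icds_hit = "", trigger_procedures_hit = ""
      ))
    }
    out <- out[match(patient_ids, out$patient_id), ]
  }
  out
}

# collect all codes on a certificate's searched fields (lines A-D + Part II)
split_codes <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, "[ ,;]+")[[1]]
}

#' Classify death certificates by flowchart
#'
#' @param deaths tibble of death certificates (see [read_deaths()]).
#' @param mortality_set [codeset()] searched on lines A-D and Part II.
#' @return tibble with one row per certificate: `person_id`, `label`
#'   (`HF_DEATH` / `POTENTIAL_HF_DEATH` / `OTHER`), `subclass`, `matched_codes`
#'   (comma-separated mortality-set prefixes found), plus `death_date`,
#'   `age_at_death`, `sex` carried through for summaries.
#' @export
classify_death <- function(deaths, mortality_set) {
  line_cols <- c("line_a", "line_b", "line_c", "line_d", "part2")
  n <- nrow(deaths)
  label <- character(n)
  subclass <- character(n)
  matched <- character(n)
  for (i in seq_len(n)) {
    lines <- unlist(lapply(deaths[i, line_cols], split_codes),
                    use.names = FALSE)
    lines <- toupper(lines)
    all_fields <- c(toupper(deaths$underlying_cause[i]), lines)
    has_i50 <- any(substr(all_fields, 1, 3) == "I50", na.rm = TRUE)
    hits <- unique(substr(lines[icd_matches(lines, mortality_set)], 1, 3))
    if (has_i50) {
      label[i] <- "HF_DEATH"
      subclass[i] <- "NONE"
      matched[i] <- ""
    } else if (length(hits)) {
      label[i] <- "POTENTIAL_HF_DEATH"
      subclass[i] <- subclassify_cause(hits)
      matched[i] <- paste(sort(hits), collapse = ",")
    } else {
      label[i] <- "OTHER"
      subclass[i] <- "NONE"
      matched[i] <- ""
    }
  }
  tibble::tibble(
    person_id = deaths$person_id,
    label = label,
    subclass = subclass,
    matched_codes = matched,
    death_date = deaths$death_date,
    age_at_death = deaths$age_at_death,
    sex = deaths$sex
  )
}

#' Subclassify the cause of a potential HF death
#'
#' Priority order when several sets match: ischaemic (I21--I25), then valvular
#' (I05--I08, I34--I39), then cardiomyopathy (I42--I44 and B57, Chagas
#' cardiomyopathy), then other cardiac (I48, I49, I51). The ischaemic-first
#' order reflects the observed predominance of infarction/ischaemia among
#' potential HF deaths.
#'
#' @param matched_codes character vector of matched 3-character prefixes.
#' @return one of `"ISCHAEMIC"`, `"VALVULAR"`, `"CARDIOMYOPATHY"`,
#'   `"OTHER_CARDIAC"`, `"NONE"` (empty input).
#' @export
subclassify_cause <- function(matched_codes) {
  if (length(matched_codes) == 0) return("NONE")
  cs <- default_codesets()
  if (any(icd_matches(matched_codes, cs$subclass_ischaemic))) return("ISCHAEMIC")
  if (any(icd_matches(matched_codes, cs$subclass_valvular))) return("VALVULAR")
  if (any(icd_matches(matched_codes, cs$subclass_cardiomyopathy))) {
    return("CARDIOMYOPATHY")
  }
  "OTHER_CARDIAC"
}

#' Yearly summary table of phenotype labels
#'
#' One row per (year, label) with patient count, mean and SD of age, male
#' count and male percentage -- the layout of the study's descriptive tables.
#'
#' @param phenotypes output of [classify_ambulatory()] (joined with
#'   demographics via `demographics`) or of [classify_death()] (which already
#'   carries age/sex; leave `demographics` NULL and set `year_from_death`).
#' @param demographics tibble with `patient_id`, `age`, `sex` for ambulatory
#'   summaries.
#' @param year_from_death if `TRUE`, the summary year is the death year.
#' @return tibble with `year`, `label`, `n`, `mean_age`, `sd_age`, `n_male`,
#'   `pct_male`. Empty (year, label) combinations are omitted.
#' @export
summarize_by_year <- function(phenotypes, demographics = NULL,
                              year_from_death = FALSE) {
  if (year_from_death) {
    dat <- dplyr::mutate(
      phenotypes,
      year = as.integer(format(.data$death_date, "%Y")),
      age = .data$age_at_death
    )
  } else {
    dat <- phenotypes |>
      dplyr::inner_join(demographics, by = "patient_id") |>
      dplyr::mutate(year = .data$classification_year)
  }
  dat |>
    dplyr::filter(!is.na(.data$year), .data$label != "NEITHER",
                  .data$label != "OTHER") |>
    dplyr::group_by(.data$year, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_age = mean(.data$age, na.rm = TRUE),
      sd_age = stats::sd(.data$age, na.rm = TRUE),
      n_male = sum(.data$sex == "male", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_male = round_half_up(100 * .data$n_male / .data$n, 2))
}

#' Male percentage implied by a printed counts table
#'
#' Recomputes `pct_male` from the `n_male` / `n` columns of a yearly counts
#' table such as [reported_yearly_counts()].
#'
#' @param counts tibble with at least `n` and `n_male`.
#' @return input with a `pct_male` column (two decimals).
#' @export
summarize_counts_table <- function(counts) {
  dplyr::mutate(counts,
                pct_male = round_half_up(100 * .data$n_male / .data$n, 2))
}

#' Concordance between proxy-identified and model-identified patients
#'
#' @param proxy_positive_ids ids flagged by the rule-based proxy.
#' @param model_positive_ids ids flagged by the risk model.
#' @return list with `overlap` (count) and `percentage`
#'   (100 * overlap / |proxy|, two decimals).
#' @export
proxy_model_concordance <- function(proxy_positive_ids, model_positive_ids) {
  proxy <- unique(proxy_positive_ids)
  if (length(proxy) == 0) stop("empty proxy set", call. = FALSE)
  ov <- length(intersect(proxy, unique(model_positive_ids)))
  list(overlap = ov,
       percentage = round_half_up(100 * ov / length(proxy), 2))
}
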