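# Tabular I/O for the three record types. CSV uses a fixed dialect (comma,
# UTF-8, ISO-8601 dates, mandatory header) so round-trips are bit-exact;
# Parquet is available when the arrow package is installed.

ambulatory_schema <- function() {
  list(
    required = c("patient_id", "event_date", "icd10"),
    optional = c("procedure"),
    col_types = readr::cols(
      patient_id = readr::col_character(),
      event_date = readr::col_date(format = "%Y-%m-%d"),
      icd10 = readr::col_character(),
      procedure = readr::col_character()
    )
  )
}

death_schema <- function() {
  list(
    required = c("person_id", "death_date", "age_at_death", "sex",
                 "underlying_cause"),
    optional = c("line_a", "line_b", "line_c", "line_d", "part2"),
    col_types = readr::cols(
      person_id = readr::col_character(),
      death_date = readr::col_date(format = "%Y-%m-%d"),
      age_at_death = readr::col_double(),
      sex = readr::col_character(),
      underlying_cause = readr::col_character(),
      line_a = readr::col_character(),
      line_b = readr::col_character(),
      line_c = readr::col_character(),
      line_d = readr::col_character(),
      part2 = readr::col_character()
    )
  )
}

demographics_schema <- function() {
  list(
    required = c("patient_id", "age", "sex", "race", "height", "weight"),
    optional = c("bmi"),
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_character(),
      race = readr::col_character(),
      height = readr::col_double(),
      weight = readr::col_double(),
      bmi = readr::col_double()
    )
  )
}

guess_format <- function(path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.parquet$", path)) "parquet" else "csv"
}

read_table_checked <- function(path, schema, format) {
  format <- guess_format(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for Parquet I/O", call. = FALSE)
    }
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    hdr <- names(readr::read_csv(path, n_max = 0,
                                 col_types = readr::cols(.default = "c"),
                                 progress = FALSE))
    ct <- schema$col_types
    ct$cols <- ct$cols[intersect(names(ct$cols), hdr)]
    readr::read_csv(path, col_types = ct, progress = FALSE)
  }
  missing <- setdiff(schema$required, names(tab))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

write_table_checked <- function(tab, path, format) {
  format <- guess_format(path, format)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for Parquet I/O", call. = FALSE)
    }
    arrow::write_parquet(tab, path)
  } else {
    readr::write_csv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Read / write ambulatory event records
#'
#' One row per billed ambulatory event: `patient_id`, `event_date` (ISO-8601),
#' `icd10` (normalized on read), and optional `procedure` identifier.
#'
#' @param path file path (`.csv` or `.parquet`).
#' @param format `"auto"` (by extension), `"csv"` or `"parquet"`.
#' @return a tibble of events.
#' @export
read_events <- function(path, format = "auto") {
  tab <- read_table_checked(path, ambulatory_schema(), format)
  tab$icd10 <- normalize_icd(tab$icd10)
  if (!"procedure" %in% names(tab)) tab$procedure <- NA_character_
  tab
}

#' @rdname read_events
#' @param events tibble of ambulatory events.
#' @export
write_events <- function(events, path, format = "auto") {
  write_table_checked(events, path, format)
}

#' Read / write death-certificate records
#'
#' One row per certificate: `person_id`, `death_date`, `age_at_death`, `sex`,
#' `underlying_cause`, Part I lines `line_a` .. `line_d` and `part2`, each a
#' space-separated list of ICD-10 codes (may be empty).
#'
#' @inheritParams read_events
#' @return a tibble of death certificates.
#' @export
read_deaths <- function(path, format = "auto") {
  tab <- read_table_checked(path, death_schema(), format)
  tab$underlying_cause <- normalize_icd(tab$underlying_cause)
  for (col in c("line_a", "line_b", "line_c", "line_d", "part2")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab
}

#' @rdname read_deaths
#' @param deaths tibble of death certificates.
#' @export
write_deaths <- function(deaths, path, format = "auto") {
  write_table_checked(deaths, path, format)
}

#' Read / write demographics records
#'
#' One row per patient: `patient_id`, `age`, `sex`, `race`, `height` (m),
#' `weight` (kg); `bmi` is derived as weight / height^2 when both are present.
#'
#' @inheritParams read_events
#' @return a tibble of demographics.
#' @export
read_demographics <- function(path, format = "auto") {
  tab <- read_table_checked(path, demographics_schema(), format)
  if (!"bmi" %in% names(tab)) {
    tab$bmi <- tab$weight / tab$height^2
  }
  tab
}

#' @rdname read_demographics
#' @param demographics tibble of demographics.
#' @export
write_demographics <- function(demographics, path, format = "auto") {
  write_table_checked(demographics, path, format)
}

#' Yearly diagnosed / potential counts printed in the source registries' report
#'
#' The per-year counts of diagnosed and potential HF patients (ambulatory
#' stream) and deaths (mortality stream), with mean age, SD and male counts,
#' shipped as a plain-text fixture. These feed [scenario_grid()] and
#' [summarize_counts_table()].
#'
#' @param path optional alternative CSV with the same columns.
#' @return tibble with columns `stream`, `label`, `year`, `n`, `mean_age`,
#'   `sd_age`, `n_male`.
#' @export
reported_yearly_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "yearly_counts.csv", package = "hfgap")
  }
  readr::read_csv(path, col_types = readr::cols(
    stream = readr::col_character(),
    label = readr::col_character(),
    year = readr::col_integer(),
    n = readr::col_double(),
    mean_age = readr::col_double(),
    sd_age = readr::col_double(),
    n_male = readr::col_double()
  ), progress = FALSE)
}
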