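# Deterministic sensitivity analysis of HF underestimation.
#
# With D diagnosed records, P potential records, and an assumed identification
# proportion p (the fraction of potential records that are genuine HF), the
# combined true caseload is D + pP and the share of it missed by official I50
# counts is
#
#   U(p) = pP / (D + pP).
#
# U(0) = 0 (best case, no potential record is real) and U(1) = P / (D + P)
# (worst case). This algebraic form reproduces all four worked scenario
# values reported for the 2018 counts (12%, 35%, 41%, 63%).

#' Underestimation rate
#'
#' @param diagnosed diagnosed count D (>= 0).
#' @param potential potential count P (>= 0).
#' @param p identification proportion in `[0, 1]`.
#' @return U(p) = pP / (D + pP) as a fraction.
#' @examples
#' underestimation_rate(72309, 49242, 0.2)  # ~0.12
#' @export
underestimation_rate <- function(diagnosed, potential, p) {
  stopifnot(all(diagnosed >= 0), all(potential >= 0),
            all(p >= 0 & p <= 1))
  denom <- diagnosed + p * potential
  if (any(denom == 0)) {
    stop("undefined underestimation rate: D + p*P = 0", call. = FALSE)
  }
  p * potential / denom
}

#' Scenario grid of underestimation rates
#'
#' Applies [underestimation_rate()] to every (year, p) combination of a yearly
#' counts table, for each stream and identification proportion, and appends a
#' pooled `ALL_YEARS` row per (stream, p) using summed counts. Rates are
#' reported both as fractions and rounded half-up to whole percent, matching
#' the reporting convention of the source tables.
#'
#' @param counts tibble with columns `stream`, `label`
#'   (`diagnosed`/`potential`), `year`, `n` -- e.g. [reported_yearly_counts()].
#' @param ps identification proportions (default 0, 0.2, ..., 1).
#' @return tibble with `stream`, `year` (integer or `"ALL_YEARS"`), `p`,
#'   `diagnosed`, `potential`, `underestimation_rate`, `underestimation_pct`.
#' @export
scenario_grid <- function(counts, ps = seq(0, 1, by = 0.2)) {
  stopifnot(nrow(counts) > 0, all(ps >= 0 & ps <= 1))
  wide <- counts |>
    dplyr::select("stream", "label", "year", "n") |>
    tidyr::pivot_wider(names_from = "label", values_from = "n")
  pooled <- wide |>
    dplyr::group_by(.data$stream) |>
    dplyr::summarise(diagnosed = sum(.data$diagnosed),
                     potential = sum(.data$potential), .groups = "drop") |>
    dplyr::mutate(year = "ALL_YEARS")
  wide <- dplyr::mutate(wide, year = as.character(.data$year))
  base <- dplyr::bind_rows(wide, pooled)
  grid <- tidyr::crossing(base, p = ps) |>
    dplyr::mutate(
      underestimation_rate = underestimation_rate(.data$diagnosed,
                                                  .data$potential, .data$p),
      underestimation_pct = round_half_up(100 * .data$underestimation_rate)
    ) |>
    dplyr::arrange(.data$stream, .data$year, .data$p)
  dplyr::select(grid, "stream", "year", "p", "diagnosed", "potential",
                "underestimation_rate", "underestimation_pct")
}

#' Validate the underestimation formula against synthetic latent truth
#'
#' On a synthetic population the identification proportion is observable:
#' `p_hat` is the fraction of POTENTIAL-labelled records whose latent status is
#' genuinely HF. The empirical underestimation (true-but-uncoded over all true
#' cases among coded + potential) must then equal `underestimation_rate(D, P,
#' p_hat)` exactly, because the formula is an algebraic identity at the
#' empirical proportion.
#'
#' @param truth latent-truth table from [generate_population()].
#' @param phenotypes ambulatory phenotypes ([classify_ambulatory()]) or
#'   mortality phenotypes ([classify_death()]); detected by column names.
#' @return list with `stream`, `diagnosed`, `potential`, `p_hat`,
#'   `empirical_underestimation`, `formula_underestimation`.
#' @export
validate_against_truth <- function(truth, phenotypes) {
  if ("patient_id" %in% names(phenotypes)) {
    stream <- "AMBULATORY"
    joined <- dplyr::inner_join(phenotypes, truth, by = "patient_id")
    diagnosed_lab <- "DIAGNOSED_HF"
    potential_lab <- "POTENTIAL_HF"
    truth_col <- "true_hf"
  } else {
    stream <- "MORTALITY"
    joined <- dplyr::inner_join(
      phenotypes, truth, by = c("person_id" = "patient_id"))
    diagnosed_lab <- "HF_DEATH"
    potential_lab <- "POTENTIAL_HF_DEATH"
    truth_col <- "true_hf_death"
  }
  D <- sum(joined$label == diagnosed_lab)
  P <- sum(joined$label == potential_lab)
  if (P == 0) stop("zero potential records", call. = FALSE)
  true_among_potential <- sum(joined$label == potential_lab &
                                joined[[truth_col]])
  p_hat <- true_among_potential / P
  empirical <- true_among_potential / (D + true_among_potential)
  list(
    stream = stream, diagnosed = D, potential = P, p_hat = p_hat,
    empirical_underestimation = empirical,
    formula_underestimation = underestimation_rate(D, P, p_hat)
  )
}
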