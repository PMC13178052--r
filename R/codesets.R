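#' Normalize a raw ICD-10 code
#'
#' Uppercases, strips the dot, and validates against the ICD-10 shape
#' (one letter, two digits, up to two optional subcode digits). Flowchart
#' logic elsewhere in the package operates on the 3-character prefix, so
#' subcodes such as `I500` keep their parent prefix `I50`.
#'
#' @param code character vector of raw ICD-10 codes (e.g. `"i50.0"`).
#' @param strict if `TRUE` (default) malformed codes raise an error naming the
#'   offending strings; if `FALSE` they are returned as `NA` with a warning.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd(c("i50.0", "I21"))
#' @export
normalize_icd <- function(code, strict = TRUE) {
  if (length(code) == 0) return(character(0))
  out <- toupper(gsub(".", "", as.character(code), fixed = TRUE))
  out <- trimws(out)
  bad <- !grepl("^[A-Z][0-9]{2}([0-9]{1,2})?$", out) | is.na(code)
  if (any(bad)) {
    msg <- paste0(
      "malformed ICD-10 code(s): ",
      paste(utils::head(unique(code[bad]), 5), collapse = ", ")
    )
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

#' Construct an ICD-10 / procedure code set
#'
#' A code set names the trigger criteria used by the phenotyping flowcharts:
#' exact 3-character ICD-10 prefixes, inclusive prefix ranges (e.g. I05--I08),
#' and/or procedure identifiers from the closed procedure vocabulary.
#'
#' @param name short identifier.
#' @param prefixes character vector of 3-character prefixes.
#' @param ranges list of length-2 character vectors `c(start, end)`; endpoints
#'   are inclusive, must share the leading letter, and `start <= end`.
#' @param procedures character vector of procedure identifiers.
#' @return an object of class `hfgap_codeset`.
#' @export
codeset <- function(name, prefixes = character(0), ranges = list(),
                    procedures = character(0)) {
  prefixes <- toupper(prefixes)
  if (length(prefixes) && any(nchar(prefixes) != 3)) {
    stop("code set prefixes must be exactly 3 characters", call. = FALSE)
  }
  ranges <- lapply(ranges, function(r) {
    r <- toupper(unlist(r))
    if (length(r) != 2 || any(nchar(r) != 3)) {
      stop("each range must be two 3-character prefixes", call. = FALSE)
    }
    if (substr(r[1], 1, 1) != substr(r[2], 1, 1) || r[1] > r[2]) {
      stop("range must share a leading letter with start <= end", call. = FALSE)
    }
    r
  })
  structure(
    list(name = name, prefixes = prefixes, ranges = ranges,
         procedures = toupper(procedures)),
    class = "hfgap_codeset"
  )
}

#' Test ICD-10 codes against a code set
#'
#' A normalized code matches when its 3-character prefix equals one of the
#' set's prefixes or falls inside any of its inclusive ranges.
#'
#' @param code character vector of normalized ICD-10 codes.
#' @param cs an [codeset()] object.
#' @return logical vector.
#' @examples
#' ms <- codeset("mortality", prefixes = "B57", ranges = list(c("I05", "I08")))
#' icd_matches(c("I070", "I500"), ms)
#' @export
icd_matches <- function(code, cs) {
  stopifnot(inherits(cs, "hfgap_codeset"))
  pre <- substr(code, 1, 3)
  hit <- pre %in% cs$prefixes
  for (r in cs$ranges) {
    hit <- hit | (pre >= r[1] & pre <= r[2])
  }
  hit & !is.na(code)
}

#' Built-in trigger code sets
#'
#' Reads the code-set definitions shipped with the package: the ambulatory
#' trigger diagnoses (I21 acute myocardial infarction, I25 chronic ischaemic
#' heart disease, I42 cardiomyopathy, I48 atrial fibrillation/flutter), the
#' ambulatory trigger procedures (natriuretic peptide testing, echocardiography,
#' cardiac catheterisation, ergospirometry, Chagas serology), and the mortality
#' search set (B57, I05--I08, I21--I25, I34--I39, I42--I44, I48, I49, I51).
#'
#' @param path optional path to an alternative JSON definition file.
#' @return named list of `hfgap_codeset` objects.
#' @export
default_codesets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codesets.json", package = "hfgap")
  }
  read_codesets(path)
}

#' Read code sets from JSON
#'
#' @param path JSON file mapping set names to `prefixes`, `ranges`,
#'   `procedures`.
#' @return named list of `hfgap_codeset` objects.
#' @export
read_codesets <- function(path) {
  raw <- jsonlite::read_json(path)
  purrr::imap(raw, function(x, nm) {
    codeset(
      name = nm,
      prefixes = unlist(x$prefixes) %||% character(0),
      ranges = x$ranges %||% list(),
      procedures = unlist(x$procedures) %||% character(0)
    )
  })
}

#' @importFrom rlang %||%
NULL

# ICD-10 chapter lookup: chapter roman numeral by 3-character prefix range.
icd10_chapters <- function() {
  tibble::tribble(
    ~chapter, ~start, ~end,
    "I",     "A00", "B99",
    "II",    "C00", "D48",
    "III",   "D50", "D89",
    "IV",    "E00", "E90",
    "V",     "F00", "F99",
    "VI",    "G00", "G99",
    "VII",   "H00", "H59",
    "VIII",  "H60", "H95",
    "IX",    "I00", "I99",
    "X",     "J00", "J99",
    "XI",    "K00", "K93",
    "XII",   "L00", "L99",
    "XIII",  "M00", "M99",
    "XIV",   "N00", "N99",
    "XV",    "O00", "O99",
    "XVI",   "P00", "P96",
    "XVII",  "Q00", "Q99",
    "XVIII", "R00", "R99",
    "XIX",   "S00", "T98",
    "XX",    "V01", "Y98",
    "XXI",   "Z00", "Z99",
    "XXII",  "U00", "U99"
  )
}

#' Map ICD-10 codes to chapters
#'
#' @param code character vector of normalized ICD-10 codes.
#' @return character vector of chapter roman numerals; codes outside every
#'   chapter range map to `"OTHER"`.
#' @export
icd_chapter <- function(code) {
  pre <- substr(code, 1, 3)
  ch <- icd10_chapters()
  out <- rep("OTHER", length(code))
  for (i in seq_len(nrow(ch))) {
    sel <- pre >= ch$start[i] & pre <= ch$end[i]
    out[sel & out == "OTHER"] <- ch$chapter[i]
  }
  out
}

#' Closed procedure vocabulary
#'
#' Procedure identifiers understood by the generator and feature builder.
#' These map to the named investigations (not to real SIGTAP codes, which are
#' out of scope): `ECHO` echocardiography, `BNP` BNP/NT-proBNP assay, `CATH`
#' cardiac catheterisation, `ERGO` ergospirometry, `CHAGAS_SERO` Trypanosoma
#' cruzi serology, `ECG` electrocardiogram, `ABPM` ambulatory blood-pressure
#' monitoring, `OTHER` anything else.
#'
#' @return character vector.
#' @export
procedure_vocabulary <- function() {
  c("ECHO", "BNP", "CATH", "ERGO", "CHAGAS_SERO", "ECG", "ABPM", "OTHER")
}
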