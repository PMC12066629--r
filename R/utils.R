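# Shared low-level helpers: name normalization, partial-date handling,
# AGE/AGE_COD conversion, dose parsing.

#' Normalize a drug name for matching
#'
#' Uppercases, replaces punctuation runs with a space and collapses repeated
#' whitespace. This is the canonical form used for primary-suspect filtering
#' and for co-medication exclusion lists. No active-ingredient dictionary is
#' applied; synonym handling is the caller's responsibility (supply all
#' spellings you want matched).
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name(c(" insulin  glargine ", "Insulin-Glargine"))
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Numeric sort key for FAERS dates that may be partial (YYYYMMDD, YYYYMM or
# YYYY). Partial dates are right-padded with "01" for *comparison only*; the
# raw text is retained on the record. Unparseable/blank -> NA.
date_sort_key <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  out <- rep(NA_real_, length(x))
  n8 <- grepl("^[0-9]{8}$", x)
  n6 <- grepl("^[0-9]{6}$", x)
  n4 <- grepl("^[0-9]{4}$", x)
  out[n8] <- as.numeric(x[n8])
  out[n6] <- as.numeric(paste0(x[n6], "01"))
  out[n4] <- as.numeric(paste0(x[n4], "0101"))
  out
}

# Full-precision (8-digit) dates -> Date; partial or blank -> NA. Used for
# time-to-onset, where day precision is required and partial dates are
# excluded rather than imputed.
parse_full_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

#' Convert FAERS AGE/AGE_COD pairs to years
#'
#' Recognizes the FAERS unit codes `YR`, `MON`, `WK`, `DY`, `DEC` and `HR`.
#' A missing unit code with `AGE <= 120` is assumed to be years (the FAERS
#' convention); converted ages outside `[0, 150)` are set to missing to guard
#' against unit errors.
#'
#' @param age Numeric or character vector of ages as reported.
#' @param cod Character vector of unit codes (may be blank).
#' @return Numeric vector of ages in years (NA where unresolvable).
#' @export
#' @examples
#' convert_age_years(c(70, 24), c("YR", "MON"))
convert_age_years <- function(age, cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(cod)))
  cod[is.na(cod)] <- ""
  mult <- c(
    YR = 1, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25,
    DEC = 10, HR = 1 / (24 * 365.25)
  )
  m <- unname(mult[cod])
  m[cod == "" & !is.na(age) & age <= 120] <- 1
  out <- age * m
  out[!is.na(out) & (out < 0 | out >= 150)] <- NA_real_
  out
}

#' Parse an insulin dose string to International Units
#'
#' Extracts the leading numeric dose from strings of the form `"20 IU"`.
#' Anything else (other units, free text, blanks) parses to `NA`; the
#' underlying reporting fields are free text and no general dose grammar is
#' attempted.
#'
#' @param x Character vector of verbatim dose strings.
#' @return Numeric vector of doses in IU (NA where unparsable).
#' @export
#' @examples
#' parse_dose_iu(c("20 IU", "20IU", "1 DF", ""))
parse_dose_iu <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([0-9]+(\\.[0-9]+)?)\\s*IU\\b", x))
  vapply(m, function(g) {
    if (length(g) >= 2) as.numeric(g[2]) else NA_real_
  }, numeric(1))
}

# Stop with a bullet list of field-level problems (used by config validators
# so every invalid field is reported at once).
stop_fieldwise <- function(errors, what) {
  if (length(errors)) {
    abort(paste0(
      "invalid ", what, ":\n",
      paste0("  - ", errors, collapse = "\n")
    ))
  }
}

is_prob_vector <- function(x, tol = 1e-9) {
  is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    all(x >= 0) && abs(sum(x) - 1) <= tol
}
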