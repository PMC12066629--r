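# Subgroup descriptive rankings (sex, age bins, country, dose) and the
# concomitant-drug-exclusion sensitivity re-screen.

AGE_BIN_LEVELS <- c("<18", "18-65", "65-85", ">85")
SEX_LEVELS <- c("male", "female")
DOSE_LEVELS <- c("10 IU", "20 IU", "30 IU", "40 IU")

# Age bins partition [0, inf): [0,18), [18,65), [65,85], (85, inf). The
# shared endpoint of the conventional 18-65 / 65-85 labels is assigned to
# the older bin so the levels are disjoint.
age_bin <- function(age_years) {
  out <- rep(NA_character_, length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 65] <- "18-65"
  out[ok & age_years >= 65 & age_years <= 85] <- "65-85"
  out[ok & age_years > 85] <- ">85"
  out
}

#' Assign each report to a stratum level
#'
#' Strata partition the reports: every report maps to exactly one level or
#' to `"missing"`. Dose strata use the parsed IU dose of the target drug's
#' primary-suspect entry, exact-matched to 10/20/30/40 IU; any other or
#' unparsable dose maps to `"other"`.
#'
#' @param ds A `faers_dataset`.
#' @param dimension One of `"sex"`, `"age"`, `"country"`, `"dose"`.
#' @param target_drug Target drug names; required for `dimension = "dose"`.
#' @return Tibble with `primaryid`, `level`.
#' @export
assign_stratum <- function(ds, dimension = c("sex", "age", "country", "dose"),
                           target_drug = NULL) {
  dimension <- match.arg(dimension)
  base <- ds$cases |> select("primaryid")
  lev <- switch(dimension,
    sex = c(male = "M", female = "F")[match(ds$cases$sex, c("M", "F"))] |>
      names(),
    age = age_bin(ds$cases$age_years),
    country = ds$cases$country,
    dose = {
      if (is.null(target_drug)) {
        abort("target_drug is required for dose strata")
      }
      nn <- normalize_drug_name(target_drug)
      dose <- ds$drugs |>
        filter(.data$role == "PS", .data$name %in% nn) |>
        group_by(.data$primaryid) |>
        summarise(dose_iu = .data$dose_iu[1], .groups = "drop")
      d <- dose$dose_iu[match(ds$cases$primaryid, dose$primaryid)]
      ifelse(!is.na(d) & d %in% c(10, 20, 30, 40),
             paste0(format(d, trim = TRUE), " IU"), "other")
    }
  )
  base$level <- ifelse(is.na(lev), "missing", lev)
  base
}

stratum_level_set <- function(ds, dimension, target_drug = NULL) {
  switch(dimension,
    sex = SEX_LEVELS,
    age = AGE_BIN_LEVELS,
    dose = c(DOSE_LEVELS, "other"),
    country = sort(unique(stats::na.omit(ds$cases$country)))
  )
}

#' Top reported events within a stratum
#'
#' Event-level PT counts (distinct report-PT pairs) within the stratum,
#' ranked by count descending with lexicographic tie-break. If `k` exceeds
#' the vocabulary observed in the stratum the full ranking is returned.
#'
#' @inheritParams assign_stratum
#' @param group The stratum level label (e.g. `"female"`, `"65-85"`,
#'   `"US"`, `"20 IU"`, or `"missing"`). An unknown label is an error.
#' @param k Number of top terms to return (`k >= 1`).
#' @return Tibble with `rank`, `pt`, `n`.
#' @export
top_events <- function(ds, dimension, group, k = 50, target_drug = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("k must be >= 1")
  st <- assign_stratum(ds, dimension, target_drug)
  allowed <- c(stratum_level_set(ds, dimension, target_drug), "missing")
  if (!group %in% allowed) {
    abort(paste0("unknown ", dimension, " level '", group, "'; expected one of: ",
                 paste(allowed, collapse = ", ")))
  }
  pids <- st$primaryid[st$level == group]
  ds$events |>
    filter(.data$primaryid %in% pids) |>
    distinct(.data$primaryid, .data$pt) |>
    count(.data$pt, name = "n") |>
    arrange(desc(.data$n), .data$pt) |>
    head(k) |>
    mutate(rank = row_number(), .before = 1)
}

#' Demographic and clinical characteristics table
#'
#' Frequency/proportion table over all cases (missing included): sex, age
#' bins, the five most-reported countries (rest pooled as `Other`),
#' reporter type, reporting year (from FDA_DT) and seriousness outcomes.
#' Percentages are per cent of all cases, to 2 decimals; a case with
#' several outcome codes counts under each, so that section may exceed
#' 100%.
#'
#' @param ds A deduplicated `faers_dataset`.
#' @return Tibble with `characteristic`, `level`, `n`, `pct`.
#' @export
demographic_table <- function(ds) {
  stopifnot(inherits(ds, "faers_dataset"))
  n_cases <- nrow(ds$cases)
  row_block <- function(characteristic, x, levels) {
    x <- ifelse(is.na(x), "missing", x)
    counts <- table(factor(x, levels = c(levels, "missing")))
    tibble(
      characteristic = characteristic,
      level = names(counts),
      n = as.integer(counts),
      pct = round(100 * as.integer(counts) / n_cases, 2)
    )
  }
  sex <- row_block("sex", c(male = "M", female = "F")[
    match(ds$cases$sex, c("M", "F"))] |> names(), SEX_LEVELS)
  age <- row_block("age", age_bin(ds$cases$age_years), AGE_BIN_LEVELS)

  ctab <- sort(table(ds$cases$country), decreasing = TRUE)
  top5 <- names(ctab)[seq_len(min(5, length(ctab)))]
  country_lab <- ifelse(is.na(ds$cases$country), NA_character_,
                        ifelse(ds$cases$country %in% top5,
                               ds$cases$country, "Other"))
  country <- row_block("country", country_lab, c(top5, "Other"))

  reporter <- row_block("reporter", ds$cases$reporter,
                        sort(unique(unname(REPORTER_DECODE))))

  yr <- substr(ds$cases$fda_dt, 1, 4)
  yr[!grepl("^[0-9]{4}$", yr)] <- NA
  year <- row_block("reporting_year", yr,
                    sort(unique(stats::na.omit(yr)), decreasing = TRUE))

  ser <- seriousness_table(ds) |>
    transmute(characteristic = "outcome", level = .data$outcome,
              n = .data$n, pct = .data$pct)

  bind_rows(
    tibble(characteristic = "cases", level = "total", n = n_cases,
           pct = 100),
    sex, age, country, reporter, year, ser
  )
}

#' Sensitivity re-screen excluding co-medicated reports
#'
#' Removes every case whose drug list mentions any excluded drug in any
#' role, then re-runs [run_screen()]. An exclusion list matching nothing
#' returns a screen identical to the primary screen.
#'
#' @inheritParams run_screen
#' @param excluded_drugs Nonempty character vector of co-medication names.
#' @return List with `screen` (the re-screen tibble), `n_reports` and
#'   `n_events` (distinct report-PT pairs) after exclusion, and
#'   `n_excluded`.
#' @export
sensitivity_screen <- function(ds, excluded_drugs, target_drug,
                               level = c("pt", "soc"), map = NULL,
                               counting = c("event", "report")) {
  if (!length(excluded_drugs) || !any(nzchar(excluded_drugs))) {
    abort("excluded_drugs must be nonempty")
  }
  nn <- normalize_drug_name(excluded_drugs)
  bad_pids <- unique(ds$drugs$primaryid[ds$drugs$name %in% nn])
  keep <- setdiff(ds$cases$primaryid, bad_pids)
  ds2 <- subset_cases(ds, keep)
  screen <- run_screen(ds2, target_drug, level = level, map = map,
                       counting = counting)
  list(
    screen = screen,
    n_reports = nrow(ds2$cases),
    n_events = nrow(distinct(ds2$events, .data$primaryid, .data$pt)),
    n_excluded = length(bad_pids)
  )
}
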