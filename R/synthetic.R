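# Synthetic FAERS-dialect report generator with planted ground truth.
#
# The generator emulates the spontaneous-report structure the screening
# pipeline consumes: one demographic row per report version, drug entries
# with role codes, PT-coded events, outcome codes, therapy start dates, a
# configurable duplicate-report rate (clones sharing CASEID with a later
# FDA_DT and a larger PRIMARYID), configurable missingness, and drug-event
# associations planted with a known odds multiplier on the per-report event
# inclusion odds of the primary-suspect drug.

#' Declare a planted drug-event association
#'
#' @param drug_name Drug (must be in the generator's drug vocabulary).
#' @param pt_term Preferred term (must be in the generator's PT vocabulary).
#' @param odds_multiplier Positive multiplier applied to the baseline
#'   per-report inclusion odds of `pt_term` for reports whose primary
#'   suspect is `drug_name`. `1` plants nothing.
#' @param expected_label Optional logical: whether the four-way intersection
#'   rule is expected to flag the pair at the configured sample size. Carried
#'   through to the truth ledger, not used by the generator itself.
#' @return A `planted_signal` object.
#' @export
#' @examples
#' planted_signal("INSULIN GLARGINE", "Hypoglycaemia", 20)
planted_signal <- function(drug_name, pt_term, odds_multiplier,
                           expected_label = NA) {
  errors <- character()
  if (!is.character(drug_name) || length(drug_name) != 1 || !nzchar(drug_name)) {
    errors <- c(errors, "drug_name: must be a single nonempty string")
  }
  if (!is.character(pt_term) || length(pt_term) != 1 || !nzchar(pt_term)) {
    errors <- c(errors, "pt_term: must be a single nonempty string")
  }
  if (!is.numeric(odds_multiplier) || length(odds_multiplier) != 1 ||
      !is.finite(odds_multiplier) || odds_multiplier <= 0) {
    errors <- c(errors, "odds_multiplier: must be a positive finite number")
  }
  stop_fieldwise(errors, "planted_signal")
  structure(
    list(
      drug_name = normalize_drug_name(drug_name), pt_term = pt_term,
      odds_multiplier = odds_multiplier, expected_label = expected_label
    ),
    class = "planted_signal"
  )
}

#' Default PT vocabulary for the synthetic generator
#'
#' Thirty preferred terms spanning nine system organ classes, weighted toward
#' the metabolic / injection-site / ophthalmic terms that dominate insulin
#' safety reporting.
#'
#' @return A tibble with columns `pt` and `soc`.
#' @export
default_pt_vocabulary <- function() {
  tribble(
    ~pt, ~soc,
    "Hypoglycaemia", "Metabolism And Nutrition Disorders",
    "Hyperglycaemia", "Metabolism And Nutrition Disorders",
    "Diabetic Ketoacidosis", "Metabolism And Nutrition Disorders",
    "Insulin Resistance", "Metabolism And Nutrition Disorders",
    "Decreased Appetite", "Metabolism And Nutrition Disorders",
    "Injection Site Pain", "General Disorders And Administration Site Conditions",
    "Injection Site Haemorrhage", "General Disorders And Administration Site Conditions",
    "Injection Site Bruising", "General Disorders And Administration Site Conditions",
    "Fatigue", "General Disorders And Administration Site Conditions",
    "Pyrexia", "General Disorders And Administration Site Conditions",
    "Visual Impairment", "Eye Disorders",
    "Cataract", "Eye Disorders",
    "Blindness", "Eye Disorders",
    "Diabetic Retinopathy", "Eye Disorders",
    "Headache", "Nervous System Disorders",
    "Dizziness", "Nervous System Disorders",
    "Memory Impairment", "Nervous System Disorders",
    "Cerebrovascular Accident", "Nervous System Disorders",
    "Nausea", "Gastrointestinal Disorders",
    "Vomiting", "Gastrointestinal Disorders",
    "Diarrhoea", "Gastrointestinal Disorders",
    "Abdominal Pain", "Gastrointestinal Disorders",
    "Rash", "Skin And Subcutaneous Tissue Disorders",
    "Pruritus", "Skin And Subcutaneous Tissue Disorders",
    "Lipodystrophy Acquired", "Skin And Subcutaneous Tissue Disorders",
    "Myocardial Infarction", "Cardiac Disorders",
    "Palpitations", "Cardiac Disorders",
    "Nasopharyngitis", "Infections And Infestations",
    "Pneumonia", "Infections And Infestations",
    "Pancreatic Neoplasm", "Neoplasms Benign, Malignant And Unspecified (Incl Cysts And Polyps)"
  )
}

default_drug_vocabulary <- function() {
  c(
    "INSULIN GLARGINE", "GLIMEPIRIDE", "METFORMIN", "SITAGLIPTIN",
    "ATORVASTATIN", "LISINOPRIL", "ASPIRIN", "OMEPRAZOLE"
  )
}

# Mildly Zipf-decaying baseline event frequencies over the PT vocabulary.
default_baseline_pt_probs <- function(n_pt) {
  w <- (seq_len(n_pt))^-0.7
  w / sum(w)
}

#' Configure the synthetic report generator
#'
#' Defaults emulate the marginal structure of insulin-glargine safety
#' reporting: demographics, reporter mix, outcome-code mix and missingness
#' rates follow published FAERS summaries for that drug, and onset times are
#' Weibull with scale 309.48 days and shape 0.54 (a decreasing-hazard,
#' early-failure regime). Sample size defaults to 20,000 reports.
#'
#' @param n_reports Number of unique cases to generate (before duplication).
#' @param duplicate_rate Probability that a case also receives a duplicate
#'   report version (same CASEID, later-or-equal FDA_DT, larger PRIMARYID,
#'   possibly one perturbed event).
#' @param drug_vocabulary Character vector of drug names.
#' @param drug_probs Primary-suspect sampling probabilities over
#'   `drug_vocabulary` (default uniform).
#' @param pt_vocabulary Tibble with columns `pt`, `soc`.
#' @param baseline_pt_probs Probability vector over `pt_vocabulary` rows
#'   (sums to 1); scaled by `events_per_report` to per-report inclusion
#'   probabilities.
#' @param events_per_report Target mean number of events per report.
#' @param planted List of [planted_signal()] objects.
#' @param concomitant_rate Per-slot probability (two slots) of an additional
#'   concomitant-role drug on a report.
#' @param tto_scale_days,tto_shape Weibull scale (days) and shape of
#'   treatment-to-onset times.
#' @param missing_age_rate,missing_sex_rate,missing_date_rate Missingness
#'   rates in `[0, 1]`; the date rate applies independently to the event date
#'   and the therapy start date.
#' @param partial_date_rate Fraction of the remaining event/start dates
#'   truncated to YYYYMM or YYYY to exercise the partial-date policy.
#' @param sex_probs Named probabilities for `M`/`F` among non-missing sexes.
#' @param country_probs,reporter_probs,outcome_probs Named probability
#'   vectors (reporter codes include a `missing` level; outcomes include a
#'   `none` level meaning no outcome row is written).
#' @param date_window Character vector of two YYYYMMDD dates bounding the
#'   therapy start dates.
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   generated files.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(n_reports = 20000,
                         duplicate_rate = 0.1,
                         drug_vocabulary = default_drug_vocabulary(),
                         drug_probs = NULL,
                         pt_vocabulary = default_pt_vocabulary(),
                         baseline_pt_probs = NULL,
                         events_per_report = 2.3,
                         planted = list(),
                         concomitant_rate = 0.35,
                         tto_scale_days = 309.48,
                         tto_shape = 0.54,
                         missing_age_rate = 0.39,
                         missing_sex_rate = 0.10,
                         missing_date_rate = 0.50,
                         partial_date_rate = 0.05,
                         sex_probs = c(M = 0.425, F = 0.575),
                         country_probs = c(
                           US = 0.857, BR = 0.021, EG = 0.010,
                           JP = 0.009, ES = 0.009, OTHER = 0.094
                         ),
                         reporter_probs = c(
                           CN = 0.816, RN = 0.042, LW = 0.001, MD = 0.047,
                           OT = 0.030, PH = 0.048, missing = 0.016
                         ),
                         outcome_probs = c(
                           DE = 0.031, LT = 0.011, HO = 0.130, DS = 0.014,
                           CA = 0.001, RI = 0.0004, OT = 0.202, none = 0.6106
                         ),
                         date_window = c("20150101", "20231231"),
                         seed = 1L) {
  if (is.null(drug_probs)) {
    drug_probs <- rep(1 / length(drug_vocabulary), length(drug_vocabulary))
  }
  if (is.null(baseline_pt_probs)) {
    baseline_pt_probs <- default_baseline_pt_probs(nrow(pt_vocabulary))
  }
  if (inherits(planted, "planted_signal")) planted <- list(planted)
  cfg <- structure(
    list(
      n_reports = n_reports, duplicate_rate = duplicate_rate,
      drug_vocabulary = normalize_drug_name(drug_vocabulary),
      drug_probs = drug_probs,
      pt_vocabulary = as_tibble(pt_vocabulary),
      baseline_pt_probs = baseline_pt_probs,
      events_per_report = events_per_report,
      planted = planted, concomitant_rate = concomitant_rate,
      tto_scale_days = tto_scale_days, tto_shape = tto_shape,
      missing_age_rate = missing_age_rate,
      missing_sex_rate = missing_sex_rate,
      missing_date_rate = missing_date_rate,
      partial_date_rate = partial_date_rate,
      sex_probs = sex_probs, country_probs = country_probs,
      reporter_probs = reporter_probs, outcome_probs = outcome_probs,
      date_window = date_window, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
  validate_synth_config(cfg)
}

#' Validate a synthetic generator configuration
#'
#' Checks every field and reports all violations together (field by field)
#' rather than stopping at the first.
#'
#' @param config A `synth_config` object.
#' @return The config, invisibly unchanged, if valid.
#' @export
validate_synth_config <- function(config) {
  e <- character()
  chk_rate <- function(x, nm, open_top = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 &&
      (if (open_top) x < 1 else x <= 1)
    if (!ok) paste0(nm, ": must be in [0,", if (open_top) "1)" else "1]") else NULL
  }
  if (!is.numeric(config$n_reports) || length(config$n_reports) != 1 ||
      config$n_reports < 1 || config$n_reports != round(config$n_reports)) {
    e <- c(e, "n_reports: must be a positive integer")
  }
  e <- c(e, chk_rate(config$duplicate_rate, "duplicate_rate", open_top = TRUE))
  for (nm in c("missing_age_rate", "missing_sex_rate", "missing_date_rate",
               "partial_date_rate", "concomitant_rate")) {
    e <- c(e, chk_rate(config[[nm]], nm))
  }
  if (!length(config$drug_vocabulary) || anyDuplicated(config$drug_vocabulary)) {
    e <- c(e, "drug_vocabulary: must be nonempty without duplicates")
  }
  if (!all(c("pt", "soc") %in% names(config$pt_vocabulary)) ||
      !nrow(config$pt_vocabulary) ||
      anyDuplicated(config$pt_vocabulary$pt)) {
    e <- c(e, "pt_vocabulary: needs pt/soc columns and unique pt values")
  }
  for (nm in c("drug_probs", "baseline_pt_probs", "sex_probs",
               "country_probs", "reporter_probs", "outcome_probs")) {
    if (!is_prob_vector(config[[nm]])) {
      e <- c(e, paste0(nm, ": must be a probability vector summing to 1 (tol 1e-9)"))
    }
  }
  if (length(config$drug_probs) != length(config$drug_vocabulary)) {
    e <- c(e, "drug_probs: length must match drug_vocabulary")
  }
  if (length(config$baseline_pt_probs) != nrow(config$pt_vocabulary)) {
    e <- c(e, "baseline_pt_probs: length must match pt_vocabulary")
  }
  for (nm in c("tto_scale_days", "tto_shape", "events_per_report")) {
    x <- config[[nm]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      e <- c(e, paste0(nm, ": must be a positive number"))
    }
  }
  for (pl in config$planted) {
    if (!inherits(pl, "planted_signal")) {
      e <- c(e, "planted: entries must be planted_signal objects")
    } else {
      if (!pl$drug_name %in% config$drug_vocabulary) {
        e <- c(e, paste0("planted: drug '", pl$drug_name, "' not in drug_vocabulary"))
      }
      if (!pl$pt_term %in% config$pt_vocabulary$pt) {
        e <- c(e, paste0("planted: PT '", pl$pt_term, "' not in pt_vocabulary"))
      }
    }
  }
  if (!all(grepl("^[0-9]{8}$", config$date_window)) ||
      length(config$date_window) != 2) {
    e <- c(e, "date_window: two YYYYMMDD strings required")
  }
  stop_fieldwise(e, "synth_config")
  invisible(config)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_reports, " reports, ",
    length(x$drug_vocabulary), " drugs, ", nrow(x$pt_vocabulary),
    " PTs, duplicate_rate=", x$duplicate_rate,
    ", planted=", length(x$planted), ", seed=", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a spontaneous-report dataset in memory
#'
#' Draws the full report set described by `config` and returns both the
#' assembled dataset (including duplicate report versions, exactly as a
#' parse of the written files would yield) and the ground-truth ledger.
#' [generate_dataset()] is a thin file-writing wrapper around this.
#'
#' @param config A [synth_config()].
#' @return A list with elements `dataset` (a `faers_dataset`), `truth`
#'   (a `faers_truth` ledger, see [truth_fourfold()]) and `raw_tables`
#'   (the six FAERS-dialect tables as tibbles of strings).
#' @export
synth_reports <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_reports)
  ptv <- config$pt_vocabulary
  J <- nrow(ptv)
  drugs <- config$drug_vocabulary

  caseid <- as.character(5000000 + seq_len(n))
  pid <- as.character(10000000 + seq_len(n) * 10)

  ps_drug <- sample(drugs, n, replace = TRUE, prob = config$drug_probs)

  ## events: independent per-PT inclusion; planted signals multiply the
  ## inclusion odds for reports whose primary suspect is the planted drug
  p_base <- pmin(config$events_per_report * config$baseline_pt_probs, 0.85)
  pmat <- matrix(p_base, nrow = n, ncol = J, byrow = TRUE)
  for (pl in config$planted) {
    j <- match(pl$pt_term, ptv$pt)
    rows <- ps_drug == pl$drug_name
    odds <- p_base[j] / (1 - p_base[j]) * pl$odds_multiplier
    pmat[rows, j] <- odds / (1 + odds)
  }
  incl <- matrix(runif(n * J), n, J) < pmat
  none <- rowSums(incl) == 0
  if (any(none)) {
    forced <- sample.int(J, sum(none), replace = TRUE,
                         prob = config$baseline_pt_probs)
    incl[cbind(which(none), forced)] <- TRUE
  }
  ev_idx <- which(incl, arr.ind = TRUE)
  ev_by_report <- split(ev_idx[, 2], factor(ev_idx[, 1], levels = seq_len(n)))

  ## demographics
  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  sex[runif(n) < config$missing_sex_rate] <- ""
  age_years <- round(pmin(pmax(rnorm(n, 62, 16), 1), 95))
  age_years[runif(n) < config$missing_age_rate] <- NA
  age_raw <- ifelse(is.na(age_years), "",
    ifelse(age_years < 2, as.character(age_years * 12),
           as.character(age_years)))
  age_cod <- ifelse(is.na(age_years), "", ifelse(age_years < 2, "MON", "YR"))
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  occp <- sample(names(config$reporter_probs), n, replace = TRUE,
                 prob = config$reporter_probs)
  occp[occp == "missing"] <- ""
  outc <- sample(names(config$outcome_probs), n, replace = TRUE,
                 prob = config$outcome_probs)

  ## therapy start, Weibull onset, event and FDA receipt dates
  win <- as.Date(config$date_window, format = "%Y%m%d")
  start_d <- win[1] + (sample.int(as.integer(win[2] - win[1]) + 1L, n,
                                  replace = TRUE) - 1L)
  onset_days <- round(rweibull(n, shape = config$tto_shape,
                               scale = config$tto_scale_days))
  event_d <- start_d + onset_days
  fda_d <- event_d + sample.int(60L, n, replace = TRUE)
  start_s <- format(start_d, "%Y%m%d")
  event_s <- format(event_d, "%Y%m%d")
  fda_s <- format(fda_d, "%Y%m%d")

  miss_ev <- runif(n) < config$missing_date_rate
  miss_st <- runif(n) < config$missing_date_rate
  part_ev <- !miss_ev & runif(n) < config$partial_date_rate
  part_st <- !miss_st & runif(n) < config$partial_date_rate
  event_s[miss_ev] <- ""
  start_s[miss_st] <- ""
  if (any(part_ev)) {
    event_s[part_ev] <- substr(event_s[part_ev], 1,
                               sample(c(6L, 4L), sum(part_ev), replace = TRUE))
  }
  if (any(part_st)) {
    start_s[part_st] <- substr(start_s[part_st], 1,
                               sample(c(6L, 4L), sum(part_st), replace = TRUE))
  }
  tto_usable <- !miss_ev & !part_ev & !miss_st & !part_st

  ## concomitant drugs (role C): up to two slots per report
  conc1 <- sample(drugs, n, replace = TRUE)
  conc2 <- sample(drugs, n, replace = TRUE)
  take <- matrix(runif(2L * n) < config$concomitant_rate, n, 2L)
  use1 <- take[, 1] & conc1 != ps_drug
  use2 <- take[, 2] & conc2 != ps_drug & conc2 != conc1

  dose_text <- sample(c("10 IU", "20 IU", "30 IU", "40 IU", ""), n,
                      replace = TRUE, prob = c(0.2, 0.25, 0.2, 0.15, 0.2))

  ## duplicate report versions: same CASEID, FDA_DT bumped by 0-90 days
  ## (0 exercises the PRIMARYID tie-break), larger PRIMARYID, and with
  ## probability 1/2 one event replaced
  is_dup <- runif(n) < config$duplicate_rate
  dup_idx <- which(is_dup)
  nd <- length(dup_idx)
  dup_pid <- as.character(10000000 + dup_idx * 10 + 1)
  dup_fda_s <- format(fda_d[dup_idx] + sample(0:90, nd, replace = TRUE),
                      "%Y%m%d")
  ev_dup <- ev_by_report[dup_idx]
  if (nd > 0) {
    perturb <- runif(nd) < 0.5
    for (k in which(perturb)) {
      evs <- ev_dup[[k]]
      evs[sample.int(length(evs), 1L)] <- sample.int(J, 1L)
      ev_dup[[k]] <- sort(unique(evs))
    }
  }
  ## after perfect deduplication the duplicate version wins (later FDA_DT,
  ## or larger PRIMARYID on a tie), so truth counts use the clone's events
  ev_ret <- ev_by_report
  ev_ret[dup_idx] <- ev_dup

  ## ---- raw FAERS-dialect tables (base rows then clone rows) ----
  demo_raw <- tibble(
    PRIMARYID = c(pid, dup_pid),
    CASEID = c(caseid, caseid[dup_idx]),
    FDA_DT = c(fda_s, dup_fda_s),
    EVENT_DT = c(event_s, event_s[dup_idx]),
    AGE = c(age_raw, age_raw[dup_idx]),
    AGE_COD = c(age_cod, age_cod[dup_idx]),
    SEX = c(sex, sex[dup_idx]),
    OCCR_COUNTRY = c(country, country[dup_idx]),
    OCCP_COD = c(occp, occp[dup_idx])
  )

  drug_base <- bind_rows(
    tibble(i = seq_len(n), DRUG_SEQ = 1L, ROLE_COD = "PS",
           DRUGNAME = ps_drug, DOSE_VBM = dose_text),
    tibble(i = which(use1), DRUG_SEQ = 2L, ROLE_COD = "C",
           DRUGNAME = conc1[use1], DOSE_VBM = ""),
    tibble(i = which(use2), DRUG_SEQ = 3L, ROLE_COD = "C",
           DRUGNAME = conc2[use2], DOSE_VBM = "")
  ) |> arrange(.data$i, .data$DRUG_SEQ)
  clone_rows <- function(base_tbl) {
    cl <- base_tbl[base_tbl$i %in% dup_idx, , drop = FALSE]
    cl$PRIMARYID <- dup_pid[match(cl$i, dup_idx)]
    cl
  }
  drug_base$PRIMARYID <- pid[drug_base$i]
  drug_raw <- bind_rows(drug_base, clone_rows(drug_base)) |>
    mutate(CASEID = caseid[.data$i]) |>
    select("PRIMARYID", "CASEID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME",
           "DOSE_VBM")

  reac_base <- tibble(
    i = rep(seq_len(n), lengths(ev_by_report)),
    PT = ptv$pt[unlist(ev_by_report, use.names = FALSE)]
  )
  reac_base$PRIMARYID <- pid[reac_base$i]
  reac_clone <- tibble(
    i = rep(dup_idx, lengths(ev_dup)),
    PT = ptv$pt[unlist(ev_dup, use.names = FALSE)]
  )
  if (nrow(reac_clone)) {
    reac_clone$PRIMARYID <- dup_pid[match(reac_clone$i, dup_idx)]
  } else {
    reac_clone$PRIMARYID <- character()
  }
  reac_raw <- bind_rows(reac_base, reac_clone) |>
    mutate(CASEID = caseid[.data$i]) |>
    select("PRIMARYID", "CASEID", "PT")

  outc_base <- tibble(i = which(outc != "none"),
                      OUTC_COD = outc[outc != "none"])
  outc_base$PRIMARYID <- pid[outc_base$i]
  outc_raw <- bind_rows(outc_base, clone_rows(outc_base)) |>
    mutate(CASEID = caseid[.data$i]) |>
    select("PRIMARYID", "CASEID", "OUTC_COD")

  ther_base <- tibble(i = seq_len(n), DSG_DRUG_SEQ = 1L, START_DT = start_s)
  ther_base$PRIMARYID <- pid[ther_base$i]
  ther_raw <- bind_rows(ther_base, clone_rows(ther_base)) |>
    mutate(CASEID = caseid[.data$i]) |>
    select("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT")

  indi_base <- tibble(i = seq_len(n), INDI_DRUG_SEQ = 1L,
                      INDI_PT = "Type 2 diabetes mellitus")
  indi_base$PRIMARYID <- pid[indi_base$i]
  indi_raw <- bind_rows(indi_base, clone_rows(indi_base)) |>
    mutate(CASEID = caseid[.data$i]) |>
    select("PRIMARYID", "CASEID", "INDI_DRUG_SEQ", "INDI_PT")

  ## ---- ground-truth ledger (on the perfectly deduplicated view) ----
  ret_events <- tibble(
    report = rep(seq_len(n), lengths(ev_ret)),
    pt = ptv$pt[unlist(ev_ret, use.names = FALSE)]
  ) |> distinct()
  ret_events$drug <- ps_drug[ret_events$report]

  a_tab <- ret_events |> count(.data$drug, .data$pt, name = "a")
  pt_tot <- ret_events |> count(.data$pt, name = "tot")
  pair_counts <- tidyr::expand_grid(drug = drugs, pt = ptv$pt) |>
    left_join(a_tab, by = c("drug", "pt")) |>
    left_join(pt_tot, by = "pt") |>
    mutate(
      a = tidyr::replace_na(.data$a, 0L),
      tot = tidyr::replace_na(.data$tot, 0L),
      c = .data$tot - .data$a
    ) |>
    select("drug", "pt", "a", "c")

  drug_totals <- tibble(drug = drugs) |>
    left_join(
      tibble(drug = ps_drug) |> count(.data$drug, name = "n_reports_ps"),
      by = "drug"
    ) |>
    left_join(
      ret_events |> count(.data$drug, name = "n_events_ps"),
      by = "drug"
    ) |>
    mutate(across(c("n_reports_ps", "n_events_ps"),
                  ~ tidyr::replace_na(.x, 0L)))

  truth <- structure(
    list(
      n_reports = n,
      n_duplicates = nd,
      duplicate_caseids = caseid[dup_idx],
      case_count = n,
      assignments = tibble(
        caseid = caseid,
        primaryid_retained = ifelse(is_dup, dup_pid[match(seq_len(n), dup_idx)],
                                    pid),
        ps_drug = ps_drug
      ),
      pair_counts = pair_counts,
      drug_totals = drug_totals,
      totals = list(
        n_cases = n,
        n_events = nrow(ret_events)
      ),
      tto = list(
        caseid = caseid[tto_usable],
        onset_days = onset_days[tto_usable],
        n_usable = sum(tto_usable),
        exclusions = c(
          event_date = sum(miss_ev | part_ev),
          start_date = sum((miss_st | part_st) & !(miss_ev | part_ev))
        )
      ),
      config = config
    ),
    class = "faers_truth"
  )

  dataset <- assemble_dataset(
    demo = demo_raw, drug = drug_raw, reac = reac_raw,
    outc = outc_raw, ther = ther_raw, indi = indi_raw,
    log = list(source = "synthetic", seed = config$seed)
  )

  list(
    dataset = dataset,
    truth = truth,
    raw_tables = list(
      demo = demo_raw, drug = drug_raw, reac = reac_raw,
      outc = outc_raw, ther = ther_raw, indi = indi_raw
    )
  )
}

#' @export
print.faers_truth <- function(x, ...) {
  cat("<faers_truth> ", x$n_reports, " cases (+", x$n_duplicates,
    " duplicate versions), ", x$totals$n_events,
    " report-PT events, TTO usable: ", x$tto$n_usable, "\n",
    sep = ""
  )
  invisible(x)
}

#' Exact fourfold table from the generator's truth ledger
#'
#' Derives the a/b/c/d cells for a (drug, PT) pair after perfect
#' deduplication, under either counting convention.
#'
#' @param truth A `faers_truth` ledger from [synth_reports()].
#' @param drug,pt The pair (drug name normalized internally).
#' @param counting `"event"` (margins count distinct report-PT pairs) or
#'   `"report"` (margins count reports).
#' @return A [fourfold_table()].
#' @export
truth_fourfold <- function(truth, drug, pt, counting = c("event", "report")) {
  counting <- match.arg(counting)
  drug <- normalize_drug_name(drug)
  row <- truth$pair_counts[truth$pair_counts$drug == drug &
                             truth$pair_counts$pt == pt, ]
  if (nrow(row) != 1) abort("pair not present in truth ledger")
  dt <- truth$drug_totals[truth$drug_totals$drug == drug, ]
  if (counting == "event") {
    t_tot <- dt$n_events_ps
    o_tot <- truth$totals$n_events - t_tot
  } else {
    t_tot <- dt$n_reports_ps
    o_tot <- truth$totals$n_cases - t_tot
  }
  fourfold_table(row$a, t_tot - row$a, row$c, o_tot - row$c)
}

#' Write a synthetic FAERS quarterly file set
#'
#' Writes the six '$'-delimited ASCII tables (`DEMO<q>.txt`, `DRUG<q>.txt`,
#' `REAC<q>.txt`, `OUTC<q>.txt`, `THER<q>.txt`, `INDI<q>.txt`), a
#' `meddra_pt_soc.tsv` PT-to-SOC map covering the generator's vocabulary,
#' and a `truth.json` ground-truth ledger. Identical seed + config gives
#' byte-identical files.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param quarter Quarter tag used in the file names, e.g. `"24Q1"`.
#' @return The `faers_truth` ledger, with the written paths in
#'   `attr(, "paths")`.
#' @export
generate_dataset <- function(config, out_dir, quarter = "24Q1") {
  validate_synth_config(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      abort(paste0("cannot create output directory: ", out_dir))
    }
  }
  sr <- synth_reports(config)
  paths <- c(
    demo = file.path(out_dir, paste0("DEMO", quarter, ".txt")),
    drug = file.path(out_dir, paste0("DRUG", quarter, ".txt")),
    reac = file.path(out_dir, paste0("REAC", quarter, ".txt")),
    outc = file.path(out_dir, paste0("OUTC", quarter, ".txt")),
    ther = file.path(out_dir, paste0("THER", quarter, ".txt")),
    indi = file.path(out_dir, paste0("INDI", quarter, ".txt"))
  )
  for (nm in names(paths)) {
    write_faers_table(sr$raw_tables[[nm]], paths[[nm]])
  }
  map_path <- file.path(out_dir, "meddra_pt_soc.tsv")
  write_meddra_map(meddra_map(config$pt_vocabulary$pt,
                              config$pt_vocabulary$soc), map_path)
  truth_path <- file.path(out_dir, "truth.json")
  tr <- sr$truth
  jsonlite::write_json(
    list(
      n_reports = tr$n_reports,
      n_duplicates = tr$n_duplicates,
      duplicate_caseids = tr$duplicate_caseids,
      assignments = tr$assignments,
      pair_counts = tr$pair_counts,
      drug_totals = tr$drug_totals,
      totals = tr$totals,
      tto = list(n_usable = tr$tto$n_usable,
                 exclusions = as.list(tr$tto$exclusions)),
      seed = config$seed
    ),
    truth_path,
    auto_unbox = TRUE, digits = NA
  )
  attr(tr, "paths") <- c(paths, meddra = map_path, truth = truth_path)
  tr
}

write_faers_table <- function(df, path) {
  readr::write_delim(df, path, delim = "$", quote = "none",
                     escape = "none", na = "")
}

#' Draw a deterministic Weibull time-to-onset sample
#'
#' @param n Number of draws (positive integer).
#' @param scale Weibull scale (days), positive.
#' @param shape Weibull shape, positive.
#' @param seed Integer seed; the same seed yields the same sequence.
#' @return Numeric vector of nonnegative onset times in days.
#' @export
#' @examples
#' x <- generate_tto_sample(1000, scale = 309.48, shape = 0.54, seed = 7)
#' median(x)
generate_tto_sample <- function(n, scale, shape, seed) {
  errors <- character()
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    errors <- c(errors, "n: must be a positive integer")
  }
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    errors <- c(errors, "scale: must be positive")
  }
  if (!is.numeric(shape) || length(shape) != 1 || !is.finite(shape) || shape <= 0) {
    errors <- c(errors, "shape: must be positive")
  }
  stop_fieldwise(errors, "generate_tto_sample arguments")
  set.seed(as.integer(seed))
  rweibull(n, shape = shape, scale = scale)
}
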