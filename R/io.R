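# Parsing FAERS-dialect quarterly ASCII tables and assembling case reports.
#
# A `faers_dataset` is a list of four tibbles sharing the PRIMARYID key:
#   cases    - one row per report version (primaryid, caseid, fda_dt,
#              event_dt, age_years, sex, country, reporter)
#   drugs    - drug entries (role PS/SS/C/I, normalized name, dose, therapy
#              start, indication)
#   events   - REAC rows (one row per reported PT, multiplicity preserved)
#   outcomes - OUTC rows (one row per outcome code)
# plus a `log` of row counts, malformed rows and orphan rows. Dates are kept
# as raw text; comparison keys and Date conversions are derived on demand so
# partial dates are never silently rewritten.

OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

REPORTER_DECODE <- c(
  CN = "consumer", RN = "nurse", LW = "lawyer", MD = "physician",
  OT = "other health professional", PH = "pharmacist"
)

MANDATORY_COLUMNS <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT"),
  drug = c("PRIMARYID", "CASEID", "ROLE_COD", "DRUGNAME"),
  reac = c("PRIMARYID", "CASEID", "PT"),
  outc = c("PRIMARYID", "CASEID", "OUTC_COD"),
  ther = c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT"),
  indi = c("PRIMARYID", "CASEID", "INDI_DRUG_SEQ", "INDI_PT")
)

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x
}

na_to_blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  trimws(x)
}

col_or <- function(df, name, default = "") {
  if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
}

# Build a faers_dataset from raw (uppercase-named, character) tables. Shared
# by parse_tables() and the synthetic generator so both paths have identical
# semantics. Malformed rows (blank PRIMARYID/CASEID) and orphan rows
# (PRIMARYID absent from DEMO) are counted in the log, never silently lost.
assemble_dataset <- function(demo, drug, reac, outc = NULL, ther = NULL,
                             indi = NULL, log = list()) {
  malformed <- c(demo = 0L, drug = 0L, reac = 0L, outc = 0L, ther = 0L,
                 indi = 0L)
  orphans <- c(drug = 0L, reac = 0L, outc = 0L, ther = 0L, indi = 0L)

  demo <- as_tibble(demo)
  demo$PRIMARYID <- na_to_blank(demo$PRIMARYID)
  demo$CASEID <- na_to_blank(demo$CASEID)
  bad <- demo$PRIMARYID == "" | demo$CASEID == ""
  malformed["demo"] <- sum(bad)
  demo <- demo[!bad, , drop = FALSE]
  pid_set <- demo$PRIMARYID

  clean_child <- function(tbl, nm) {
    if (is.null(tbl)) {
      return(tibble(PRIMARYID = character(), CASEID = character()))
    }
    tbl <- as_tibble(tbl)
    tbl$PRIMARYID <- na_to_blank(tbl$PRIMARYID)
    tbl$CASEID <- na_to_blank(tbl$CASEID)
    bad <- tbl$PRIMARYID == "" | tbl$CASEID == ""
    malformed[nm] <<- sum(bad)
    tbl <- tbl[!bad, , drop = FALSE]
    orphan <- !tbl$PRIMARYID %in% pid_set
    orphans[nm] <<- sum(orphan)
    tbl[!orphan, , drop = FALSE]
  }
  drug <- clean_child(drug, "drug")
  reac <- clean_child(reac, "reac")
  outc <- clean_child(outc, "outc")
  ther <- clean_child(ther, "ther")
  indi <- clean_child(indi, "indi")

  sex_raw <- toupper(na_to_blank(col_or(demo, "SEX")))
  occp <- toupper(na_to_blank(col_or(demo, "OCCP_COD")))
  cases <- tibble(
    primaryid = demo$PRIMARYID,
    caseid = demo$CASEID,
    fda_dt = na_to_blank(col_or(demo, "FDA_DT")),
    event_dt = na_to_blank(col_or(demo, "EVENT_DT")),
    age_years = convert_age_years(col_or(demo, "AGE", NA_character_),
                                  col_or(demo, "AGE_COD")),
    sex = ifelse(sex_raw %in% c("M", "F"), sex_raw, NA_character_),
    country = blank_to_na(col_or(demo, "OCCR_COUNTRY")),
    reporter = unname(REPORTER_DECODE[occp])
  )

  ther_key <- if (nrow(ther)) {
    tibble(
      primaryid = ther$PRIMARYID,
      drug_seq = suppressWarnings(as.integer(col_or(ther, "DSG_DRUG_SEQ", NA))),
      start_dt = na_to_blank(col_or(ther, "START_DT"))
    ) |>
      filter(.data$start_dt != "") |>
      distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE)
  } else {
    tibble(primaryid = character(), drug_seq = integer(),
           start_dt = character())
  }
  indi_key <- if (nrow(indi)) {
    tibble(
      primaryid = indi$PRIMARYID,
      drug_seq = suppressWarnings(as.integer(col_or(indi, "INDI_DRUG_SEQ", NA))),
      indication = blank_to_na(col_or(indi, "INDI_PT"))
    ) |> distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE)
  } else {
    tibble(primaryid = character(), drug_seq = integer(),
           indication = character())
  }

  drugs <- tibble(
    primaryid = drug$PRIMARYID,
    caseid = drug$CASEID,
    drug_seq = suppressWarnings(as.integer(col_or(drug, "DRUG_SEQ", NA))),
    name = normalize_drug_name(na_to_blank(col_or(drug, "DRUGNAME"))),
    name_raw = na_to_blank(col_or(drug, "DRUGNAME")),
    role = toupper(na_to_blank(col_or(drug, "ROLE_COD"))),
    dose_text = na_to_blank(col_or(drug, "DOSE_VBM"))
  ) |>
    mutate(dose_iu = parse_dose_iu(.data$dose_text)) |>
    left_join(ther_key, by = c("primaryid", "drug_seq")) |>
    left_join(indi_key, by = c("primaryid", "drug_seq")) |>
    mutate(start_dt = ifelse(is.na(.data$start_dt), "", .data$start_dt))

  events <- tibble(
    primaryid = reac$PRIMARYID,
    caseid = reac$CASEID,
    pt = na_to_blank(col_or(reac, "PT"))
  ) |> filter(.data$pt != "")

  outcomes <- tibble(
    primaryid = outc$PRIMARYID,
    caseid = outc$CASEID,
    outc_cod = toupper(na_to_blank(col_or(outc, "OUTC_COD")))
  ) |> filter(.data$outc_cod != "")

  structure(
    list(
      cases = cases, drugs = drugs, events = events, outcomes = outcomes,
      log = c(log, list(malformed = malformed, orphans = orphans))
    ),
    class = "faers_dataset"
  )
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("<faers_dataset> ", nrow(x$cases), " report versions (",
    dplyr::n_distinct(x$cases$caseid), " cases), ",
    nrow(x$drugs), " drug entries, ", nrow(x$events), " event rows, ",
    nrow(x$outcomes), " outcome rows\n",
    sep = ""
  )
  orph <- x$log$orphans
  if (!is.null(orph) && sum(orph) > 0) {
    cat("  orphan rows excluded:",
        paste0(names(orph)[orph > 0], "=", orph[orph > 0], collapse = ", "),
        "\n")
  }
  invisible(x)
}

read_faers_file <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_delim(
    path, delim = "$", quote = "",
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  names(tbl) <- toupper(trimws(names(tbl)))
  tbl
}

#' Parse FAERS-dialect quarterly tables into a dataset
#'
#' Reads one or more files per table (multiple quarters concatenate), checks
#' mandatory columns, counts malformed and orphan rows in the dataset log,
#' and assembles case reports.
#'
#' @param paths Named list of file paths. Names (case-insensitive):
#'   `demo`, `drug`, `reac` (mandatory) and optionally `outc`, `ther`,
#'   `indi`. Each element may be a character vector of several files.
#' @return A `faers_dataset` (not yet deduplicated).
#' @seealso [deduplicate()], [filter_primary_suspect()], [faers_file_set()]
#' @export
parse_tables <- function(paths) {
  names(paths) <- tolower(names(paths))
  missing_tabs <- setdiff(c("demo", "drug", "reac"), names(paths))
  if (length(missing_tabs)) {
    abort(paste0("missing mandatory table(s): ",
                 paste(toupper(missing_tabs), collapse = ", ")))
  }
  raw <- list()
  for (nm in intersect(c("demo", "drug", "reac", "outc", "ther", "indi"),
                       names(paths))) {
    tbl <- bind_rows(lapply(paths[[nm]], read_faers_file))
    need <- MANDATORY_COLUMNS[[nm]]
    absent <- setdiff(need, names(tbl))
    if (length(absent)) {
      abort(paste0(toupper(nm), " table is missing mandatory column(s): ",
                   paste(absent, collapse = ", ")))
    }
    raw[[nm]] <- tbl
  }
  assemble_dataset(
    demo = raw$demo, drug = raw$drug, reac = raw$reac,
    outc = raw$outc, ther = raw$ther, indi = raw$indi,
    log = list(
      source = "files",
      files = lapply(paths, as.character),
      rows_read = vapply(raw, nrow, integer(1))
    )
  )
}

#' Locate a quarterly file set in a directory
#'
#' Globs `DEMO*.txt`, `DRUG*.txt`, ... under `dir` and returns the named
#' list [parse_tables()] expects.
#'
#' @param dir Directory containing the ASCII tables.
#' @return Named list of file path vectors.
#' @export
faers_file_set <- function(dir) {
  pick <- function(stem) {
    f <- sort(list.files(dir, pattern = paste0("^", stem, ".*\\.(txt|TXT)$"),
                         full.names = TRUE))
    if (length(f)) f else NULL
  }
  out <- list(
    demo = pick("DEMO"), drug = pick("DRUG"), reac = pick("REAC"),
    outc = pick("OUTC"), ther = pick("THER"), indi = pick("INDI")
  )
  out[!vapply(out, is.null, logical(1))]
}

# Restrict every table of a dataset to the given report versions.
subset_cases <- function(ds, keep_pids) {
  ds$cases <- ds$cases[ds$cases$primaryid %in% keep_pids, , drop = FALSE]
  for (nm in c("drugs", "events", "outcomes")) {
    ds[[nm]] <- ds[[nm]][ds[[nm]]$primaryid %in% keep_pids, , drop = FALSE]
  }
  ds
}

#' Deduplicate case reports by the FDA rule
#'
#' Among report versions sharing a CASEID the version with the largest
#' FDA_DT is retained; on an FDA_DT tie, the largest PRIMARYID wins.
#' Partial FDA dates are right-padded with "01" for comparison only.
#' Idempotent; output ordered by caseid.
#'
#' @param ds A `faers_dataset`.
#' @return The dataset with one report per caseid.
#' @export
deduplicate <- function(ds) {
  stopifnot(inherits(ds, "faers_dataset"))
  key <- date_sort_key(ds$cases$fda_dt)
  if (anyNA(key)) {
    abort(paste0("FDA_DT not comparable for ", sum(is.na(key)),
                 " report(s); deduplication needs an orderable FDA date"))
  }
  pid_num <- suppressWarnings(as.numeric(ds$cases$primaryid))
  if (anyNA(pid_num)) pid_num <- rank(ds$cases$primaryid, ties.method = "min")
  keep <- ds$cases |>
    mutate(.key = key, .pid = pid_num) |>
    arrange(.data$caseid, .data$.key, .data$.pid) |>
    group_by(.data$caseid) |>
    slice_tail(n = 1) |>
    ungroup()
  out <- subset_cases(ds, keep$primaryid)
  out$cases <- out$cases |> arrange(.data$caseid)
  out
}

# PRIMARYIDs of reports listing any of the target drugs as primary suspect.
ps_case_pids <- function(ds, drug_names) {
  nn <- normalize_drug_name(drug_names)
  unique(ds$drugs$primaryid[ds$drugs$role == "PS" & ds$drugs$name %in% nn])
}

#' Filter a dataset to reports with a target primary-suspect drug
#'
#' A report is retained when at least one of its drug entries has role `PS`
#' and a normalized name matching one of `drug_names` (matching is
#' case-insensitive after whitespace/punctuation normalization). A report
#' mentioning the target drug under several roles is counted once.
#'
#' @param ds A `faers_dataset`.
#' @param drug_names Nonempty character vector of target drug names
#'   (include every synonym/spelling you want matched).
#' @return The filtered dataset.
#' @export
filter_primary_suspect <- function(ds, drug_names) {
  stopifnot(inherits(ds, "faers_dataset"))
  if (!length(drug_names) || !any(nzchar(drug_names))) {
    abort("drug_names must be a nonempty character vector")
  }
  subset_cases(ds, ps_case_pids(ds, drug_names))
}

#' Construct a MedDRA PT-to-SOC map
#'
#' MedDRA itself is licensed and is not shipped; the caller supplies the
#' mapping (each PT to its primary SOC).
#'
#' @param pt Character vector of preferred terms (unique).
#' @param soc Character vector of system organ classes, same length.
#' @return A `meddra_map` object.
#' @export
meddra_map <- function(pt, soc) {
  if (length(pt) != length(soc)) abort("pt and soc must have equal length")
  if (anyDuplicated(pt)) {
    abort(paste0("duplicate PT key(s) in map: ",
                 paste(unique(pt[duplicated(pt)]), collapse = ", ")))
  }
  structure(tibble(pt = as.character(pt), soc = as.character(soc)),
            class = c("meddra_map", "tbl_df", "tbl", "data.frame"))
}

#' Read a PT-to-SOC map from a two-column TSV
#'
#' The file has columns PT and SOC (a header row named `pt`/`soc` in any
#' case is recognized; otherwise the first row is taken as data).
#'
#' @param path Path to the TSV.
#' @return A `meddra_map`.
#' @export
read_meddra_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readr::read_tsv(path, n_max = 1, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  has_header <- ncol(first) >= 2 &&
    all(tolower(unlist(first[1, 1:2])) %in% c("pt", "soc"))
  tbl <- readr::read_tsv(
    path, col_names = if (has_header) TRUE else c("pt", "soc"),
    skip = 0, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  names(tbl) <- tolower(names(tbl))
  meddra_map(tbl$pt, tbl$soc)
}

#' Write a PT-to-SOC map as TSV
#' @param map A `meddra_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meddra_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path, progress = FALSE)
  invisible(path)
}

#' Annotate events with their system organ class
#'
#' Row-wise join of the event table against the PT-to-SOC map; event
#' multiplicity is preserved (one output row per REAC row). PTs absent from
#' the map are routed to the `"UNMAPPED"` bucket with a warning.
#'
#' @param ds A `faers_dataset`.
#' @param map A [meddra_map()].
#' @return A tibble with columns `primaryid`, `caseid`, `pt`, `soc`.
#' @export
annotate_soc <- function(ds, map) {
  stopifnot(inherits(ds, "faers_dataset"), inherits(map, "meddra_map"))
  out <- ds$events |>
    left_join(as_tibble(map), by = "pt")
  n_unmapped <- sum(is.na(out$soc))
  if (n_unmapped > 0) {
    warn(paste0(n_unmapped, " event row(s) with PT absent from the map ",
                "routed to SOC 'UNMAPPED'"))
    out$soc[is.na(out$soc)] <- "UNMAPPED"
  }
  out
}

#' Seriousness categories of each case
#'
#' Pass-through of validated OUTC codes (DE, LT, HO, DS, CA, RI, OT) per
#' case; a case with no recognized outcome row is labelled missing.
#' Unrecognized codes are excluded from the tallies and their count is
#' attached as `attr(, "unrecognized")`.
#'
#' @param ds A `faers_dataset`.
#' @return Tibble with `primaryid`, `caseid`, `outcomes` (list column of
#'   code subsets) and `missing` (logical).
#' @export
classify_seriousness <- function(ds) {
  stopifnot(inherits(ds, "faers_dataset"))
  oc <- ds$outcomes
  unrecognized <- sum(!oc$outc_cod %in% OUTCOME_CODES)
  oc <- oc |>
    filter(.data$outc_cod %in% OUTCOME_CODES) |>
    distinct(.data$primaryid, .data$outc_cod)
  sets <- split(oc$outc_cod, oc$primaryid)
  out <- ds$cases |>
    select("primaryid", "caseid") |>
    mutate(
      outcomes = unname(sets[.data$primaryid]),
      missing = vapply(.data$outcomes, is.null, logical(1))
    )
  out$outcomes[out$missing] <- list(character())
  attr(out, "unrecognized") <- unrecognized
  out
}

#' Frequency table of seriousness categories
#'
#' Case-level tally: a case counts once under each outcome code it carries;
#' cases with no recognized code count under `Missing`. Proportions are over
#' all cases, so rows can sum to more than 100% when cases carry several
#' codes.
#'
#' @param ds A `faers_dataset`.
#' @return Tibble with `outcome`, `n`, `pct` (2 decimals).
#' @export
seriousness_table <- function(ds) {
  cls <- classify_seriousness(ds)
  n_cases <- nrow(cls)
  counts <- table(factor(unlist(cls$outcomes), levels = OUTCOME_CODES))
  tibble(
    outcome = c(OUTCOME_CODES, "Missing"),
    n = c(as.integer(counts), sum(cls$missing))
  ) |>
    mutate(pct = round(100 * .data$n / n_cases, 2))
}

#' Export an assembled dataset as a columnar file set
#'
#' Writes `cases.csv`, `drugs.csv`, `events.csv` and `outcomes.csv` with the
#' documented column names of the `faers_dataset` tables.
#'
#' @param ds A `faers_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "faers_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cases = file.path(dir, "cases.csv"),
    drugs = file.path(dir, "drugs.csv"),
    events = file.path(dir, "events.csv"),
    outcomes = file.path(dir, "outcomes.csv")
  )
  readr::write_csv(ds$cases, paths["cases"], progress = FALSE)
  readr::write_csv(ds$drugs, paths["drugs"], progress = FALSE)
  readr::write_csv(ds$events, paths["events"], progress = FALSE)
  readr::write_csv(ds$outcomes, paths["outcomes"], progress = FALSE)
  invisible(paths)
}
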