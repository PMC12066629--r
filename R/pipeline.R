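# One-shot pipeline: simulate (or read) -> parse -> deduplicate -> screen ->
# time-to-onset -> demographics -> strata -> sensitivity, with a manifest of
# settings and artifact digests. The command-line entry point at
# inst/scripts/faerspv.R is a thin wrapper over these functions.

#' Configure a pipeline run
#'
#' Exactly one of `input` (paths to existing FAERS-dialect tables) or
#' `synthetic` (a [synth_config()] to simulate from) must be supplied.
#' Validation problems are aggregated and reported together.
#'
#' @param out_dir Output directory for artifacts.
#' @param input Named list of table paths as for [parse_tables()], or NULL.
#' @param synthetic A [synth_config()], or NULL.
#' @param target_drug Character vector of target drug names.
#' @param meddra_map_path Path to a PT-to-SOC TSV; required when `"soc"` is
#'   among `levels` and the run is not synthetic (synthetic runs write and
#'   use the generator's own map).
#' @param levels Screen levels, subset of `c("pt", "soc")`.
#' @param counting `"event"` or `"report"` (see [run_screen()]).
#' @param strata Stratum dimensions to rank, subset of
#'   `c("sex", "age", "country", "dose")`.
#' @param top_k Ranking depth for [top_events()].
#' @param exclude_drugs Co-medications for the sensitivity re-screen
#'   (empty vector skips it).
#' @param seed Integer seed (synthetic runs).
#' @return A validated `run_config` object.
#' @export
run_config <- function(out_dir,
                       input = NULL,
                       synthetic = NULL,
                       target_drug = "INSULIN GLARGINE",
                       meddra_map_path = NULL,
                       levels = c("pt", "soc"),
                       counting = "event",
                       strata = c("sex", "age"),
                       top_k = 50,
                       exclude_drugs = c("GLIMEPIRIDE", "METFORMIN",
                                         "SITAGLIPTIN"),
                       seed = 1L) {
  e <- character()
  if (is.null(input) == is.null(synthetic)) {
    e <- c(e, "exactly one of input / synthetic must be set")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synth_config")) {
    e <- c(e, "synthetic: must be a synth_config object")
  }
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1) {
    e <- c(e, "out_dir: a single output directory is required")
  }
  if (!is.null(input)) {
    if (!is.list(input) || is.null(names(input))) {
      e <- c(e, "input: must be a named list of table paths")
    } else if (!is.character(out_dir) ||
               any(normalizePath(dirname(unlist(input)), mustWork = FALSE) ==
                   suppressWarnings(normalizePath(out_dir, mustWork = FALSE)))) {
      e <- c(e, "out_dir: must be distinct from the input directory")
    }
  }
  if (!all(levels %in% c("pt", "soc")) || !length(levels)) {
    e <- c(e, "levels: subset of pt/soc required")
  }
  if (!counting %in% c("event", "report")) {
    e <- c(e, "counting: must be 'event' or 'report'")
  }
  if (!all(strata %in% c("sex", "age", "country", "dose"))) {
    e <- c(e, "strata: allowed dimensions are sex/age/country/dose")
  }
  if ("soc" %in% levels && is.null(synthetic) && is.null(meddra_map_path)) {
    e <- c(e, "meddra_map_path: required for a SOC-level screen on file input")
  }
  if (!length(target_drug) || !any(nzchar(target_drug))) {
    e <- c(e, "target_drug: nonempty drug name(s) required")
  }
  stop_fieldwise(e, "run_config")
  structure(
    list(
      out_dir = out_dir, input = input, synthetic = synthetic,
      target_drug = target_drug, meddra_map_path = meddra_map_path,
      levels = levels, counting = counting, strata = strata,
      top_k = top_k, exclude_drugs = exclude_drugs, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; a `synthetic`
#' sub-object holds [synth_config()] arguments (with `planted` given as a
#' list of `{drug_name, pt_term, odds_multiplier}` records).
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$synthetic)) {
    sargs <- raw$synthetic
    if (!is.null(sargs$planted)) {
      pl <- sargs$planted
      if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
      sargs$planted <- lapply(pl, function(p) {
        planted_signal(p$drug_name, p$pt_term, p$odds_multiplier,
                       p$expected_label %||% NA)
      })
    }
    if (!is.null(sargs$pt_vocabulary)) {
      sargs$pt_vocabulary <- as_tibble(sargs$pt_vocabulary)
    }
    raw$synthetic <- do.call(synth_config, sargs)
  }
  raw <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, raw)
}

log_info <- function(...) inform(paste0("INFO ", ...))

#' Run the full screening pipeline
#'
#' Executes every stage on the configured input and writes the artifact
#' set under `config$out_dir`: per-level screen CSVs, `tto_summary.json`
#' and `tto_histogram.csv`, `demographics.csv`, per-stratum ranking CSVs,
#' a sensitivity re-screen CSV, and `manifest.json` recording package
#' version, settings, dataset sizes at each checkpoint and an MD5 digest of
#' every artifact. Deterministic for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `screens`, `tto`, `fit`, `demographics`, `strata`, `sensitivity`,
#'   `manifest`, `artifacts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- character()

  if (!is.null(config$synthetic)) {
    sim_dir <- file.path(out_dir, "input")
    scfg <- config$synthetic
    scfg$seed <- config$seed
    log_info("simulating ", scfg$n_reports, " reports into ", sim_dir)
    truth <- generate_dataset(scfg, sim_dir)
    paths <- faers_file_set(sim_dir)
    map <- read_meddra_map(attr(truth, "paths")[["meddra"]])
  } else {
    paths <- config$input
    map <- if (!is.null(config$meddra_map_path)) {
      read_meddra_map(config$meddra_map_path)
    } else {
      NULL
    }
    truth <- NULL
  }

  ds <- parse_tables(paths)
  n_parsed <- nrow(ds$cases)
  log_info("parsed: ", n_parsed, " report versions, ",
           nrow(ds$events), " event rows")
  ds <- deduplicate(ds)
  log_info("deduplicated: ", nrow(ds$cases), " cases")
  ps <- filter_primary_suspect(ds, config$target_drug)
  log_info("primary-suspect filtered: ", nrow(ps$cases), " cases")

  screens <- list()
  for (lv in config$levels) {
    scr <- run_screen(ds, config$target_drug, level = lv, map = map,
                      counting = config$counting)
    screens[[lv]] <- scr
    p <- file.path(out_dir, paste0("screen_", lv, ".csv"))
    write_screen(scr, p)
    artifacts <- c(artifacts, p)
    log_info("screen at ", toupper(lv), ": ", nrow(scr), " terms, ",
             sum(scr$positive), " positive")
  }

  tto <- compute_tto(ps, config$target_drug)
  fit <- if (nrow(tto$records) >= 10) fit_weibull(tto) else NULL
  tto_paths <- write_tto(tto, fit, out_dir)
  artifacts <- c(artifacts, unname(tto_paths))
  log_info("time to onset: ", nrow(tto$records), " usable records")

  demo <- demographic_table(ps)
  p <- file.path(out_dir, "demographics.csv")
  readr::write_csv(demo, p, progress = FALSE)
  artifacts <- c(artifacts, p)

  strata_out <- list()
  for (dim in config$strata) {
    groups <- c(stratum_level_set(ps, dim, config$target_drug), "missing")
    tab <- bind_rows(lapply(groups, function(g) {
      top_events(ps, dim, g, k = config$top_k,
                 target_drug = config$target_drug) |>
        mutate(group = g, .before = 1)
    }))
    strata_out[[dim]] <- tab
    p <- file.path(out_dir, paste0("top_events_", dim, ".csv"))
    readr::write_csv(tab, p, progress = FALSE)
    artifacts <- c(artifacts, p)
  }

  sens <- NULL
  if (length(config$exclude_drugs)) {
    sens <- sensitivity_screen(ds, config$exclude_drugs, config$target_drug,
                               level = config$levels[1], map = map,
                               counting = config$counting)
    p <- file.path(out_dir, paste0("sensitivity_", config$levels[1], ".csv"))
    write_screen(sens$screen, p)
    artifacts <- c(artifacts, p)
    log_info("sensitivity: ", sens$n_reports, " reports, ", sens$n_events,
             " events after excluding ", sens$n_excluded, " reports")
  }

  manifest <- list(
    package = "faerspv",
    version = as.character(packageVersion("faerspv")),
    r_version = as.character(getRversion()),
    settings = list(
      target_drug = config$target_drug, levels = config$levels,
      counting = config$counting, strata = config$strata,
      exclude_drugs = config$exclude_drugs, seed = config$seed,
      synthetic = !is.null(config$synthetic)
    ),
    checkpoints = list(
      parsed_versions = n_parsed,
      deduplicated_cases = nrow(ds$cases),
      ps_filtered_cases = nrow(ps$cases),
      tto_records = nrow(tto$records)
    ),
    inputs = lapply(paths, function(f) {
      list(files = as.character(f), md5 = unname(tools::md5sum(f)))
    }),
    artifacts = lapply(setNames(artifacts, basename(artifacts)), function(f) {
      unname(tools::md5sum(f))
    })
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)

  invisible(list(
    dataset = ds, ps_dataset = ps, screens = screens, tto = tto, fit = fit,
    demographics = demo, strata = strata_out, sensitivity = sens,
    truth = truth, manifest = manifest,
    artifacts = c(artifacts, mp)
  ))
}
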