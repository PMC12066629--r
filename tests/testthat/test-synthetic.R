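# Synthetic generator: config validation, file dialect, determinism,
# ground-truth ledger consistency, planted associations, onset sampling.

test_that("invalid configs are reported field by field", {
  err <- tryCatch(
    synth_config(n_reports = 0, duplicate_rate = 1.2,
                 missing_age_rate = -0.1),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "n_reports")
  expect_match(err, "duplicate_rate")
  expect_match(err, "missing_age_rate")

  expect_error(
    synth_config(planted = list(
      planted_signal("NOT A DRUG", "Hypoglycaemia", 2)
    )),
    "not in drug_vocabulary"
  )
  expect_error(planted_signal("A", "B", -1), "odds_multiplier")
})

test_that("generated DEMO row count equals cases plus realized duplicates", {
  out1 <- withr::local_tempdir()
  truth1 <- generate_dataset(synth_config(n_reports = 100, duplicate_rate = 0,
                                          seed = 1), out1)
  demo1 <- readr::read_delim(file.path(out1, "DEMO24Q1.txt"), delim = "$",
                             quote = "", show_col_types = FALSE)
  expect_identical(nrow(demo1), 100L)
  expect_identical(truth1$n_duplicates, 0L)

  out2 <- withr::local_tempdir()
  truth2 <- generate_dataset(synth_config(n_reports = 1000,
                                          duplicate_rate = 0.1, seed = 7),
                             out2)
  demo2 <- readr::read_delim(file.path(out2, "DEMO24Q1.txt"), delim = "$",
                             quote = "", show_col_types = FALSE)
  expect_identical(nrow(demo2), 1000L + truth2$n_duplicates)
  expect_gt(truth2$n_duplicates, 0L)
})

test_that("identical seed and config give byte-identical files", {
  cfg <- small_config(n = 300, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  d3 <- withr::local_tempdir()
  generate_dataset(small_config(n = 300, seed = 100), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "DEMO24Q1.txt"))),
    unname(tools::md5sum(file.path(d3, "DEMO24Q1.txt")))
  ))
})

test_that("round-trip: parse + deduplicate recovers the truth ledger", {
  cfg <- small_config(n = 800, duplicate_rate = 0.15, seed = 21)
  out <- withr::local_tempdir()
  truth <- generate_dataset(cfg, out)
  ds <- parse_tables(faers_file_set(out))

  # every REAC row's report exists in DEMO (no orphans from the generator)
  expect_identical(sum(ds$log$orphans), 0L)

  dd <- deduplicate(ds)
  expect_identical(nrow(dd$cases), truth$case_count)
  expect_setequal(dd$cases$caseid, truth$assignments$caseid)
  # retained versions are exactly the ledger's (clone wins)
  expect_setequal(dd$cases$primaryid, truth$assignments$primaryid_retained)

  # primary-suspect counts match the ledger drug by drug
  for (dg in c("INSULIN GLARGINE", "METFORMIN")) {
    n_ps <- nrow(filter_primary_suspect(dd, dg)$cases)
    expect_identical(
      n_ps,
      as.integer(truth$drug_totals$n_reports_ps[
        truth$drug_totals$drug == dg])
    )
  }
})

test_that("downstream fourfold tables equal truth cells for both countings", {
  cfg <- small_config(
    n = 1500, duplicate_rate = 0.1, seed = 5,
    planted = list(planted_signal("INSULIN GLARGINE", "Cataract", 6))
  )
  sr <- synth_reports(cfg)
  dd <- deduplicate(sr$dataset)
  pairs <- list(
    c("INSULIN GLARGINE", "Cataract"),
    c("INSULIN GLARGINE", "Hypoglycaemia"),
    c("METFORMIN", "Nausea"),
    c("ASPIRIN", "Pneumonia")
  )
  for (pr in pairs) {
    for (cm in c("event", "report")) {
      want <- truth_fourfold(sr$truth, pr[1], pr[2], counting = cm)
      got <- build_contingency(dd, pr[1], pr[2], level = "pt", counting = cm)
      expect_equal(unlist(got), unlist(want),
                   info = paste(pr[1], pr[2], cm))
    }
  }
})

test_that("planted odds multiplier is recovered from truth counts", {
  cfg <- synth_config(
    n_reports = 5000, duplicate_rate = 0, seed = 31,
    planted = list(planted_signal("INSULIN GLARGINE",
                                  "Lipodystrophy Acquired", 20))
  )
  sr <- synth_reports(cfg)
  t <- truth_fourfold(sr$truth, "INSULIN GLARGINE", "Lipodystrophy Acquired",
                      counting = "report")
  or <- (t$a * t$d) / (t$b * t$c)
  expect_gt(or, 20 * 0.7)
  expect_lt(or, 20 / 0.7)
})

test_that("outcome code frequencies follow the configured probabilities", {
  cfg <- small_config(n = 5000, duplicate_rate = 0, seed = 13)
  sr <- synth_reports(cfg)
  cls <- classify_seriousness(sr$dataset)
  lev <- names(cfg$outcome_probs)
  obs <- table(factor(
    vapply(cls$outcomes, function(o) if (length(o)) o[[1]] else "none",
           character(1)),
    levels = lev
  ))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(obs), p = unname(cfg$outcome_probs))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("Weibull onset sampler matches its closed forms and is deterministic", {
  # shape 1 is exponential: mean equals the scale
  x <- generate_tto_sample(100000, scale = 100, shape = 1, seed = 3)
  expect_equal(mean(x), 100, tolerance = 0.02)
  expect_true(all(x >= 0))

  # median converges to scale * ln(2)^(1/shape)
  y <- generate_tto_sample(100000, scale = 309.48, shape = 0.54, seed = 4)
  expect_equal(median(y), 309.48 * log(2)^(1 / 0.54), tolerance = 0.03)

  expect_identical(generate_tto_sample(50, 300, 0.54, seed = 9),
                   generate_tto_sample(50, 300, 0.54, seed = 9))
  expect_error(generate_tto_sample(0, 300, 0.54, 1), "positive")
  expect_error(generate_tto_sample(10, -1, 0.54, 1), "scale")
})

test_that("time-to-onset exclusion tally matches the generator ledger", {
  cfg <- small_config(n = 1200, duplicate_rate = 0.1, seed = 17)
  sr <- synth_reports(cfg)
  dd <- deduplicate(sr$dataset)
  ps <- filter_primary_suspect(dd, "INSULIN GLARGINE")
  tto <- compute_tto(ps, "INSULIN GLARGINE")

  ps_cases <- sr$truth$assignments$caseid[
    sr$truth$assignments$ps_drug == "INSULIN GLARGINE"]
  usable <- intersect(sr$truth$tto$caseid, ps_cases)
  expect_identical(nrow(tto$records), length(usable))
  expect_identical(sum(tto$exclusions), length(ps_cases) - length(usable))
  expect_identical(unname(tto$exclusions["negative"]), 0L)
  # onset values agree record by record
  want <- sr$truth$tto$onset_days[match(sort(usable), sr$truth$tto$caseid)]
  got <- tto$records$onset_days[match(sort(usable), tto$records$caseid)]
  expect_equal(got, want)
})
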