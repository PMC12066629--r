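# Time to onset: calendar arithmetic, exclusion accounting, summaries,
# Weibull maximum likelihood and failure-type classification.

tto_fixture <- function() {
  demo <- tibble::tibble(
    PRIMARYID = c("1", "2", "3", "4", "5"),
    CASEID = c("1", "2", "3", "4", "5"),
    FDA_DT = "20200601",
    EVENT_DT = c("20200131", "20200101", "202003", "", "20200110"),
    AGE = "", AGE_COD = "", SEX = "", OCCR_COUNTRY = "", OCCP_COD = ""
  )
  drug <- tibble::tibble(
    PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID, DRUG_SEQ = "1",
    ROLE_COD = "PS", DRUGNAME = "DRUGA", DOSE_VBM = ""
  )
  ther <- tibble::tibble(
    PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID, DSG_DRUG_SEQ = "1",
    START_DT = c("20200101", "20200301", "20200101", "20200101", "20200110")
  )
  reac <- tibble::tibble(PRIMARYID = "1", CASEID = "1", PT = "PT1")
  parse_tables(write_faers_fixture(tempfile(), demo, drug, reac,
                                   ther = ther))
}

test_that("onset is event minus earliest start, with tallied exclusions", {
  tto <- compute_tto(tto_fixture(), "DRUGA")
  rec <- tto$records
  expect_equal(rec$onset_days[rec$primaryid == "1"], 30)
  expect_equal(rec$onset_days[rec$primaryid == "5"], 0) # same-day onset kept
  expect_false("2" %in% rec$primaryid) # event before start
  expect_false("3" %in% rec$primaryid) # partial event date
  expect_false("4" %in% rec$primaryid) # missing event date
  expect_identical(unname(tto$exclusions),
                   c(2L, 0L, 1L)) # event_date, start_date, negative
})

test_that("earliest therapy start anchors multi-episode reports", {
  demo <- tibble::tibble(
    PRIMARYID = "1", CASEID = "1", FDA_DT = "20200601",
    EVENT_DT = "20200301", AGE = "", AGE_COD = "", SEX = "",
    OCCR_COUNTRY = "", OCCP_COD = ""
  )
  drug <- tibble::tibble(
    PRIMARYID = "1", CASEID = "1", DRUG_SEQ = c("1", "2"),
    ROLE_COD = c("PS", "SS"), DRUGNAME = "DRUGA", DOSE_VBM = ""
  )
  ther <- tibble::tibble(
    PRIMARYID = "1", CASEID = "1", DSG_DRUG_SEQ = c("1", "2"),
    START_DT = c("20200201", "20200101")
  )
  reac <- tibble::tibble(PRIMARYID = "1", CASEID = "1", PT = "PT1")
  ds <- parse_tables(write_faers_fixture(tempfile(), demo, drug, reac,
                                         ther = ther))
  tto <- compute_tto(ds, "DRUGA")
  expect_equal(tto$records$onset_days, 60) # from the earliest start
})

test_that("summaries use 30-day bins and type-7 quantiles", {
  s <- summarize_tto(c(10, 20, 400))
  expect_equal(s$first_month_prop, 2 / 3)
  expect_equal(s$median, 20)
  expect_equal(sum(s$histogram$proportion), 1)
  expect_equal(s$first_month_prop, s$histogram$proportion[1]) # bin-1 mass

  one <- summarize_tto(158)
  expect_equal(one$median, 158)
  expect_equal(unname(one$iqr), c(158, 158))

  x <- c(1, 31, 61, 91)
  expect_equal(summarize_tto(x)$histogram$count, c(1, 1, 1, 1))
  expect_equal(summarize_tto(x)$median, unname(quantile(x, 0.5, type = 7)))
  expect_error(summarize_tto(numeric()), "no onset")
})

test_that("Weibull fit recovers parameters and matches an independent fitter", {
  x <- generate_tto_sample(20000, scale = 300, shape = 0.54, seed = 41)
  fit <- fit_weibull(x)
  expect_equal(fit$beta, 0.54, tolerance = 0.02)
  expect_equal(fit$alpha, 300, tolerance = 0.02)
  expect_true(fit$beta_ci["low"] <= fit$beta &&
                fit$beta <= fit$beta_ci["high"])

  # independent oracle: fitdistrplus MLE on a smaller sample
  y <- generate_tto_sample(5000, scale = 120, shape = 1.7, seed = 42)
  ours <- fit_weibull(y)
  ref <- fitdistrplus::fitdist(y, "weibull")
  expect_equal(ours$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(ours$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("fit is scale-equivariant and beats random parameter probes", {
  x <- generate_tto_sample(3000, scale = 200, shape = 0.8, seed = 11)
  f1 <- fit_weibull(x)
  f2 <- fit_weibull(x * 7)
  expect_equal(f2$alpha / f1$alpha, 7, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)

  # likelihood at the optimum dominates 100 random probes
  xs <- x
  xs[xs == 0] <- 0.5
  ll <- function(al, be) {
    sum(stats::dweibull(xs, shape = be, scale = al, log = TRUE))
  }
  set.seed(8)
  probes <- replicate(100, ll(stats::runif(1, 10, 2000),
                              stats::runif(1, 0.2, 5)))
  expect_true(all(f1$loglik >= probes))
})

test_that("Wald CIs achieve near-nominal coverage for exponential truth", {
  # 200 replicates keep the Monte Carlo error of the observed coverage
  # rate well inside the 90% acceptance bound for a nominal 95% interval
  reps <- 200L
  hits <- 0L
  for (r in seq_len(reps)) {
    x <- generate_tto_sample(500, scale = 100, shape = 1, seed = 1000 + r)
    f <- fit_weibull(x)
    if (f$beta_ci["low"] <= 1 && 1 <= f$beta_ci["high"]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})

test_that("degenerate inputs produce diagnostics, zeros are shifted", {
  expect_error(fit_weibull(c(5, 5, 5)), "identical")
  expect_error(fit_weibull(7), "at least 2")
  f <- fit_weibull(c(0, 0, rep(c(3, 10, 45), 20)))
  expect_identical(f$n_zero_shifted, 2L)
})

test_that("failure types follow the shape CI rule", {
  mk <- function(beta, lo, hi) {
    list(beta = beta, beta_ci = c(low = lo, high = hi))
  }
  expect_identical(classify_failure_type(mk(0.54, 0.53, 0.55)), "early")
  expect_identical(classify_failure_type(mk(1.0, 0.9, 1.1)), "constant")
  expect_identical(classify_failure_type(mk(1.4, 1.2, 1.6)), "wear_out")
  expect_identical(classify_failure_type(mk(0.98, 0.95, 1.02)), "constant")

  x <- generate_tto_sample(20000, scale = 300, shape = 0.54, seed = 2)
  expect_identical(fit_weibull(x)$failure_type, "early")
})
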