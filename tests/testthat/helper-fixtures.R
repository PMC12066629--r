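# Fixture builders (all in code; files are written to tempdirs at test
# time) and the independent direct-arithmetic oracle for the four
# disproportionality statistics.

write_faers_fixture <- function(dir, demo, drug, reac, outc = NULL,
                                ther = NULL, indi = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
               THER = ther, INDI = indi)
  for (stem in names(tabs)) {
    if (!is.null(tabs[[stem]])) {
      readr::write_delim(tabs[[stem]],
                         file.path(dir, paste0(stem, "24Q1.txt")),
                         delim = "$", quote = "none", escape = "none",
                         na = "")
    }
  }
  faers_file_set(dir)
}

# Four reports, two drugs, two PTs; six (report, PT) events in total.
# Hand-enumerated cells for target DRUGA / term PT1:
#   event-level:  a=2 (r1, r2), b=1 (r1 PT2), c=1 (r4), d=2 (r3, r4 PT2)
#   report-level: a=2, b=0, c=1, d=1
toy_event_fixture <- function(dir = tempfile("toy")) {
  demo <- tibble::tibble(
    PRIMARYID = c("101", "102", "103", "104"),
    CASEID = c("1", "2", "3", "4"),
    FDA_DT = "20200101", EVENT_DT = "", AGE = "", AGE_COD = "",
    SEX = "", OCCR_COUNTRY = "", OCCP_COD = ""
  )
  drug <- tibble::tibble(
    PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID, DRUG_SEQ = "1",
    ROLE_COD = "PS",
    DRUGNAME = c("DRUGA", "DRUGA", "DRUGB", "DRUGB"), DOSE_VBM = ""
  )
  reac <- tibble::tibble(
    PRIMARYID = c("101", "101", "102", "103", "104", "104"),
    CASEID = c("1", "1", "2", "3", "4", "4"),
    PT = c("PT1", "PT2", "PT1", "PT2", "PT1", "PT2")
  )
  parse_tables(write_faers_fixture(dir, demo, drug, reac))
}

toy_map <- function() {
  meddra_map(
    pt = c("PT1", "PT2", "Hypoglycaemia"),
    soc = c("SOC1", "SOC2", "Metabolism And Nutrition Disorders")
  )
}

# Independent oracle: the four statistics by plain scalar arithmetic,
# written directly from the printed formulas (no shared code with the
# package's vectorized implementation).
oracle_disprop <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a * (c + d)) / (c * (a + b))
  chi2 <- ((a * d - b * c)^2 * n) / ((a + b) * (c + d) * (a + c) * (b + d))
  ebgm <- (a * n) / ((a + c) * (a + b))
  list(
    ror = ror,
    ror_low = exp(log(ror) - 1.96 * se),
    ror_high = exp(log(ror) + 1.96 * se),
    prr = prr, chi2 = chi2, ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - 1.96 * se),
    ic = log(ebgm) / log(2),
    ic025 = log(ebgm) / log(2) - 2 * (se / log(2))
  )
}

# Random strictly-positive fourfold tables for property tests.
random_tables <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    a = sample(1:200, n, replace = TRUE),
    b = sample(1:2000, n, replace = TRUE),
    c = sample(1:2000, n, replace = TRUE),
    d = sample(1:50000, n, replace = TRUE)
  )
}

small_config <- function(n = 1000, ...) {
  synth_config(n_reports = n, ...)
}
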