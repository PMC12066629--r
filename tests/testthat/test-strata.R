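# Subgroup rankings, demographic tables, and the sensitivity re-screen.

strata_fixture <- function() {
  demo <- tibble::tibble(
    PRIMARYID = as.character(1:10),
    CASEID = as.character(1:10),
    FDA_DT = c(rep("20200101", 5), rep("20210601", 5)),
    EVENT_DT = "",
    AGE = c("10", "18", "65", "85", "86", "40", "", "70", "30", "90"),
    AGE_COD = "YR",
    SEX = c("F", "F", "F", "F", "M", "M", "M", "M", "M", ""),
    OCCR_COUNTRY = c(rep("US", 6), "BR", "BR", "EG", ""),
    OCCP_COD = c(rep("CN", 8), "MD", "")
  )
  drug <- tibble::tibble(
    PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID, DRUG_SEQ = "1",
    ROLE_COD = "PS", DRUGNAME = "DRUGA",
    DOSE_VBM = c("10 IU", "10 IU", "20 IU", "40 IU", "1 DF",
                 "30 IU", "", "20 IU", "10 IU", "20 IU")
  )
  reac <- tibble::tibble(
    PRIMARYID = c("1", "1", "2", "3", "4", "5", "6", "7", "8", "10"),
    CASEID = c("1", "1", "2", "3", "4", "5", "6", "7", "8", "10"),
    PT = c("A", "B", "A", "B", "C", "A", "B", "A", "B", "C")
  )
  parse_tables(write_faers_fixture(tempfile(), demo, drug, reac))
}

test_that("age bins partition with the documented boundary assignment", {
  ds <- strata_fixture()
  st <- assign_stratum(ds, "age")
  lev <- st$level[match(as.character(1:10), st$primaryid)]
  expect_identical(lev[1], "<18") # 10
  expect_identical(lev[2], "18-65") # 18 inclusive
  expect_identical(lev[3], "65-85") # 65 goes to the older bin
  expect_identical(lev[4], "65-85") # 85 inclusive
  expect_identical(lev[5], ">85") # 86
  expect_identical(lev[7], "missing")
})

test_that("top_events ranks by count with lexicographic tie-break", {
  ds <- strata_fixture()
  # male stratum (cases 5-9): PTs A:{5,7}, B:{6,8}, C:{} -> tie A,B
  top <- top_events(ds, "sex", "male", k = 2)
  expect_identical(top$pt, c("A", "B"))
  expect_identical(top$n, c(2L, 2L))

  # k larger than vocabulary: full ranking, no padding
  all_f <- top_events(ds, "sex", "female", k = 50)
  expect_identical(nrow(all_f), 3L)

  expect_error(top_events(ds, "sex", "unknown_level"), "unknown sex level")
  expect_error(top_events(ds, "dose", "10 IU"), "target_drug")
})

test_that("stratified event counts are conserved against the overall total", {
  cfg <- small_config(n = 600, duplicate_rate = 0, seed = 33)
  ds <- deduplicate(synth_reports(cfg)$dataset)
  total <- nrow(dplyr::distinct(ds$events, primaryid, pt))
  by_sex <- vapply(
    c("male", "female", "missing"),
    function(g) sum(top_events(ds, "sex", g, k = 1000)$n),
    integer(1)
  )
  expect_identical(sum(by_sex), total)
})

test_that("dose strata exact-match parsed IU doses", {
  ds <- strata_fixture()
  st <- assign_stratum(ds, "dose", target_drug = "DRUGA")
  lev <- st$level[match(as.character(1:10), st$primaryid)]
  expect_identical(lev[1], "10 IU")
  expect_identical(lev[5], "other") # "1 DF" unparsable
  expect_identical(lev[7], "other") # blank dose
  top <- top_events(ds, "dose", "10 IU", k = 10, target_drug = "DRUGA")
  expect_identical(sum(top$n), 3L) # cases 1 (A,B) and 2 (A); case 9 has no event
})

test_that("demographic table reports proportions over all cases", {
  ds <- strata_fixture()
  tab <- demographic_table(ds)
  fem <- tab[tab$characteristic == "sex" & tab$level == "female", ]
  expect_identical(fem$n, 4L)
  expect_equal(fem$pct, 40.00)
  ctry <- tab[tab$characteristic == "country" & tab$level == "BR", ]
  expect_identical(ctry$n, 2L)
  yr <- tab[tab$characteristic == "reporting_year", ]
  expect_identical(yr$level[1:2], c("2021", "2020"))

  # all ages missing -> 100% missing
  ds2 <- ds
  ds2$cases$age_years <- NA_real_
  tab2 <- demographic_table(ds2)
  miss <- tab2[tab2$characteristic == "age" & tab2$level == "missing", ]
  expect_equal(miss$pct, 100)
})

test_that("sensitivity screen removes co-medicated cases role-agnostically", {
  demo <- tibble::tibble(
    PRIMARYID = as.character(1:5), CASEID = as.character(1:5),
    FDA_DT = "20200101", EVENT_DT = "", AGE = "", AGE_COD = "", SEX = "",
    OCCR_COUNTRY = "", OCCP_COD = ""
  )
  drug <- dplyr::bind_rows(
    tibble::tibble(PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID,
                   DRUG_SEQ = "1", ROLE_COD = "PS", DRUGNAME = "DRUGA",
                   DOSE_VBM = ""),
    tibble::tibble(PRIMARYID = c("2", "4"), CASEID = c("2", "4"),
                   DRUG_SEQ = "2", ROLE_COD = "C", DRUGNAME = "METFORMIN",
                   DOSE_VBM = "")
  )
  reac <- tibble::tibble(PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID,
                         PT = c("A", "A", "B", "B", "A"))
  ds <- parse_tables(write_faers_fixture(tempfile(), demo, drug, reac))

  sens <- sensitivity_screen(ds, "metformin", "DRUGA")
  expect_identical(sens$n_reports, 3L)
  expect_identical(sens$n_excluded, 2L)

  # exclusion list with no matches reproduces the primary screen
  prim <- run_screen(ds, "DRUGA")
  noop <- sensitivity_screen(ds, "NOT PRESENT", "DRUGA")
  expect_equal(as.data.frame(noop$screen), as.data.frame(prim))

  # term universe of the re-screen is contained in the primary screen's
  expect_true(all(sens$screen$term %in% prim$term))
  expect_error(sensitivity_screen(ds, character(), "DRUGA"), "nonempty")
})
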