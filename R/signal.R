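# Disproportionality statistics on drug-event fourfold tables.
#
# The four screening statistics and their thresholds:
#   ROR  = ad/(bc),            flag if 95% CI lower bound > 1 and a >= 3
#   PRR  = a(c+d)/(c(a+b)),    flag if PRR >= 2, chi2 >= 4 and a >= 3
#   IC   = log2(aN/((a+c)(a+b))), flag if IC025 > 0
#   EBGM = aN/((a+c)(a+b)),    flag if EBGM05 > 2
# A pair is a positive signal only when all four criteria hold. CIs for ROR
# and EBGM are Wald intervals on the log scale; IC025 uses the delta-method
# variance V(IC) = (1/a+1/b+1/c+1/d)/ln(2)^2 (see the methods vignette: the
# IC point estimate is exactly log2(EBGM); the bound is frequentist, not a
# Bayesian BCPNN posterior quantile). No zero-cell continuity correction is
# applied anywhere: statistics undefined at zero cells fail their criterion.

#' Construct a fourfold (2x2) contingency table
#'
#' Cell conventions: `a` = target drug with the target term, `b` = target
#' drug with other terms, `c` = other drugs with the target term, `d` =
#' other drugs with other terms.
#'
#' @param a,b,c,d Nonnegative integer counts; `a+b+c+d >= 1`.
#' @return A `fourfold_table` object.
#' @export
#' @examples
#' fourfold_table(10, 90, 100, 9900)
fourfold_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!is.numeric(cells) || length(cells) != 4 || anyNA(cells) ||
      any(cells < 0) || any(cells != round(cells))) {
    abort("a, b, c, d must be nonnegative integers")
  }
  if (sum(cells) < 1) abort("table total must be at least 1")
  structure(as.list(as.numeric(cells)) |> setNames(c("a", "b", "c", "d")),
            class = "fourfold_table")
}

#' @export
print.fourfold_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("target term", "other terms")))
  print(m)
  invisible(x)
}

# Vectorized core: all four statistics and their bounds from cell vectors.
# Undefined quantities (zero cells in a denominator or in the CI radical)
# are NA; criteria treat NA as failed. Computation is in double precision
# throughout; rounding to 2 decimals is display-only.
disprop_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  all_pos <- a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(all_pos, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)

  ror <- ifelse(b > 0 & c > 0, (a * d) / (b * c), NA_real_)
  ror_low <- ifelse(all_pos, ror * exp(-1.96 * se), NA_real_)
  ror_high <- ifelse(all_pos, ror * exp(1.96 * se), NA_real_)

  prr <- ifelse(c > 0 & (a + b) > 0, (a * (c + d)) / (c * (a + b)), NA_real_)
  marg <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(marg > 0, (a * d - b * c)^2 * n / marg, NA_real_)

  ebgm <- ifelse(a > 0 & (a + c) > 0 & (a + b) > 0,
                 a * n / ((a + c) * (a + b)), NA_real_)
  ebgm05 <- ifelse(all_pos, exp(log(ebgm) - 1.96 * se), NA_real_)

  ic <- ifelse(!is.na(ebgm) & ebgm > 0, log2(ebgm), NA_real_)
  ic025 <- ifelse(all_pos, ic - 2 * (se / log(2)), NA_real_)

  tibble(
    a = a, b = b, c = c, d = d, n = n,
    ror = ror, ror_low = ror_low, ror_high = ror_high,
    prr = prr, chi2 = chi2,
    ic = ic, ic025 = ic025,
    ebgm = ebgm, ebgm05 = ebgm05
  )
}

# Vectorized threshold flags; NA statistics fail their criterion.
signal_flags <- function(s) {
  flag <- function(x) !is.na(x) & x
  s |>
    mutate(
      crit_ror = flag(.data$ror_low > 1) & .data$a >= 3,
      crit_prr = flag(.data$prr >= 2) & flag(.data$chi2 >= 4) & .data$a >= 3,
      crit_ic = flag(.data$ic025 > 0),
      crit_ebgm = flag(.data$ebgm05 > 2),
      positive = .data$crit_ror & .data$crit_prr & .data$crit_ic &
        .data$crit_ebgm
    )
}

as_stat_row <- function(t) {
  stopifnot(inherits(t, "fourfold_table"))
  disprop_stats(t$a, t$b, t$c, t$d)
}

#' Reporting odds ratio with 95% CI
#'
#' `ROR = ad/(bc)`; the CI is `exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' A zero in `b` or `c` leaves the estimate undefined; a zero anywhere
#' leaves the CI undefined. Undefined values are returned as `NA` and
#' flagged, never corrected.
#'
#' @param t A [fourfold_table()].
#' @return List with `estimate`, `ci` (low, high), `defined`.
#' @export
#' @examples
#' ror(fourfold_table(10, 90, 100, 9900))
ror <- function(t) {
  s <- as_stat_row(t)
  list(estimate = s$ror, ci = c(low = s$ror_low, high = s$ror_high),
       defined = !is.na(s$ror_low))
}

#' Proportional reporting ratio with chi-squared
#'
#' `PRR = a(c+d)/(c(a+b))`; the companion statistic is
#' `chi2 = (ad-bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d))`, without
#' continuity correction.
#'
#' @param t A [fourfold_table()].
#' @return List with `estimate`, `chi2`, `defined`.
#' @export
prr <- function(t) {
  s <- as_stat_row(t)
  list(estimate = s$prr, chi2 = s$chi2,
       defined = !is.na(s$prr) & !is.na(s$chi2))
}

#' Information component with its lower bound
#'
#' `IC = log2(aN/((a+c)(a+b)))` (identically `log2(EBGM)`), with
#' `IC025 = IC - 2 sqrt(V(IC))` under the delta-method variance
#' `V(IC) = (1/a+1/b+1/c+1/d)/ln(2)^2`.
#'
#' @param t A [fourfold_table()].
#' @return List with `ic`, `ic025`, `defined`.
#' @export
bcpnn_ic <- function(t) {
  s <- as_stat_row(t)
  list(ic = s$ic, ic025 = s$ic025, defined = !is.na(s$ic025))
}

#' Observed-to-expected EBGM with its lower bound
#'
#' `EBGM = aN/((a+c)(a+b))` (the observed/expected ratio form), with
#' `EBGM05 = exp(ln EBGM - 1.96 sqrt(1/a+1/b+1/c+1/d))`. This is not the
#' gamma-Poisson shrinkage estimator; see the methods vignette.
#'
#' @param t A [fourfold_table()].
#' @return List with `ebgm`, `ebgm05`, `defined`.
#' @export
mgps_ebgm <- function(t) {
  s <- as_stat_row(t)
  list(ebgm = s$ebgm, ebgm05 = s$ebgm05, defined = !is.na(s$ebgm05))
}

#' Apply the four-way intersection positivity rule
#'
#' A pair is a positive signal only when all four criteria hold
#' simultaneously; any undefined statistic fails its criterion.
#'
#' @param t A [fourfold_table()].
#' @return List with `positive` and the four `per_criterion` booleans.
#' @export
#' @examples
#' classify_signal(fourfold_table(10, 90, 100, 9900))
classify_signal <- function(t) {
  s <- signal_flags(as_stat_row(t))
  list(
    positive = s$positive,
    per_criterion = c(ror = s$crit_ror, prr = s$crit_prr,
                      ic = s$crit_ic, ebgm = s$crit_ebgm)
  )
}

# Per-term a/c counts plus margins for a screen. Events are counted at the
# requested level as *distinct (report, term)* pairs: a report listing one
# PT twice, or two PTs of one SOC at SOC level, contributes once.
screen_event_counts <- function(ds, target_drug, level = c("pt", "soc"),
                                map = NULL) {
  level <- match.arg(level)
  if (!nrow(ds$cases)) abort("dataset has no cases")
  if (level == "soc") {
    if (is.null(map)) abort("a meddra_map is required for a SOC-level screen")
    ev <- annotate_soc(ds, map) |> transmute(.data$primaryid, term = .data$soc)
  } else {
    ev <- ds$events |> transmute(.data$primaryid, term = .data$pt)
  }
  ev <- ev |> distinct()
  targets <- ps_case_pids(ds, target_drug)
  ev$is_target <- ev$primaryid %in% targets
  counts <- ev |>
    count(.data$term, .data$is_target) |>
    tidyr::pivot_wider(names_from = "is_target", values_from = "n",
                       values_fill = 0L)
  for (nm in c("TRUE", "FALSE")) {
    if (!nm %in% names(counts)) counts[[nm]] <- 0L
  }
  counts <- counts |> rename(a = "TRUE", c = "FALSE")
  list(
    counts = counts,
    n_target_events = sum(counts$a),
    n_other_events = sum(counts$c),
    n_target_reports = sum(ds$cases$primaryid %in% targets),
    n_other_reports = sum(!ds$cases$primaryid %in% targets)
  )
}

margins_for <- function(sc, counting) {
  if (counting == "event") {
    c(t = sc$n_target_events, o = sc$n_other_events)
  } else {
    c(t = sc$n_target_reports, o = sc$n_other_reports)
  }
}

#' Build the fourfold table for one drug-term pair
#'
#' @param ds A deduplicated `faers_dataset` containing both the target
#'   drug's reports and the comparator reports.
#' @param target_drug Character vector of target drug names (synonyms).
#' @param term The PT (or SOC) of interest; a term absent from the data
#'   yields `a = 0`, not an error.
#' @param level `"pt"` or `"soc"`.
#' @param map A [meddra_map()], required for SOC level.
#' @param counting `"event"`: margins count distinct (report, term) pairs;
#'   `"report"`: margins count reports.
#' @return A [fourfold_table()].
#' @export
build_contingency <- function(ds, target_drug, term, level = c("pt", "soc"),
                              map = NULL, counting = c("event", "report")) {
  counting <- match.arg(counting)
  sc <- screen_event_counts(ds, target_drug, level, map)
  row <- sc$counts[sc$counts$term == term, ]
  a <- if (nrow(row)) row$a else 0L
  c <- if (nrow(row)) row$c else 0L
  m <- margins_for(sc, counting)
  fourfold_table(a, m[["t"]] - a, c, m[["o"]] - c)
}

#' Screen every term for disproportionate reporting
#'
#' Builds the fourfold table of every term with at least one target-drug
#' event, computes the four statistics with their bounds, and applies the
#' intersection positivity rule. Ordering is deterministic: descending
#' target count `a`, then term lexicographic.
#'
#' @inheritParams build_contingency
#' @return A tibble with one row per term: `term`, `level`, the cells, the
#'   statistics (`ror`, `ror_low`, `ror_high`, `prr`, `chi2`, `ic`, `ic025`,
#'   `ebgm`, `ebgm05`), per-criterion flags and `positive`. Dataset margins
#'   are attached as `attr(, "totals")`.
#' @export
run_screen <- function(ds, target_drug, level = c("pt", "soc"), map = NULL,
                       counting = c("event", "report")) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  sc <- screen_event_counts(ds, target_drug, level, map)
  m <- margins_for(sc, counting)
  rows <- sc$counts |> filter(.data$a >= 1)
  out <- disprop_stats(rows$a, m[["t"]] - rows$a, rows$c,
                       m[["o"]] - rows$c) |>
    signal_flags() |>
    mutate(term = rows$term, level = level, .before = 1) |>
    arrange(desc(.data$a), .data$term)
  attr(out, "totals") <- c(
    m, n_cases = nrow(ds$cases),
    n_target_events = sc$n_target_events,
    n_other_events = sc$n_other_events
  )
  attr(out, "counting") <- counting
  out
}

#' Write a screen to CSV with display rounding
#'
#' Estimates are rounded to 2 decimals for display, mirroring the usual
#' presentation of signal tables; the in-memory screen keeps full precision.
#'
#' @param screen A screen tibble from [run_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  out <- screen |>
    mutate(across(c("ror", "ror_low", "ror_high", "prr", "chi2",
                    "ic", "ic025", "ebgm", "ebgm05"),
                  ~ round(.x, 2)))
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}
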