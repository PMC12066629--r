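# Time-to-onset: days from therapy initiation to the reported event, one
# record per case, summarized and fit with a two-parameter Weibull.
#
# The Weibull shape governs the hazard trend of adverse events over
# treatment time: shape < 1 with its whole CI below 1 is an early-failure
# pattern (event rate highest at the start of therapy and declining),
# a CI containing 1 is a constant rate, and shape > 1 with its CI above 1
# is wear-out (risk growing with treatment duration).

#' Compute time to onset per case
#'
#' Onset is the difference in days between the report's event date and the
#' earliest full-precision therapy start date of the target drug on that
#' report ("treatment initiation"). Records with missing or partial dates,
#' or a negative difference, are excluded and tallied by reason; exclusions
#' are data, not errors.
#'
#' @param ds A deduplicated, primary-suspect-filtered `faers_dataset` whose
#'   drug entries carry therapy start dates.
#' @param target_drug Character vector of target drug names.
#' @return List with `records` (tibble `primaryid`, `caseid`, `onset_days`)
#'   and `exclusions` (named counts: `event_date`, `start_date`,
#'   `negative`).
#' @export
compute_tto <- function(ds, target_drug) {
  stopifnot(inherits(ds, "faers_dataset"))
  nn <- normalize_drug_name(target_drug)
  starts <- ds$drugs |>
    filter(.data$name %in% nn) |>
    mutate(start_date = parse_full_date(.data$start_dt)) |>
    filter(!is.na(.data$start_date)) |>
    group_by(.data$primaryid) |>
    summarise(start_date = min(.data$start_date), .groups = "drop")
  rec <- ds$cases |>
    select("primaryid", "caseid", "event_dt") |>
    mutate(event_date = parse_full_date(.data$event_dt)) |>
    left_join(starts, by = "primaryid")
  no_event <- is.na(rec$event_date)
  no_start <- !no_event & is.na(rec$start_date)
  rec <- rec |>
    filter(!is.na(.data$event_date), !is.na(.data$start_date)) |>
    mutate(onset_days = as.numeric(.data$event_date - .data$start_date))
  negative <- rec$onset_days < 0
  list(
    records = rec |>
      filter(.data$onset_days >= 0) |>
      select("primaryid", "caseid", "onset_days"),
    exclusions = c(
      event_date = sum(no_event),
      start_date = sum(no_start),
      negative = sum(negative)
    )
  )
}

as_onset_vector <- function(x) {
  if (is.list(x) && !is.null(x$records)) x <- x$records
  if (is.data.frame(x)) x <- x$onset_days
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    abort("onset days must be finite and nonnegative")
  }
  x
}

#' Summarize time-to-onset records
#'
#' Median and interquartile range use linear interpolation (the type-7
#' quantile convention). The histogram uses 30-day bins `[0,30]`,
#' `(30,60]`, ...; the first-month proportion is exactly the mass of the
#' first bin.
#'
#' @param x Onset days: a numeric vector, a records tibble, or the result
#'   of [compute_tto()].
#' @return List with `n`, `median`, `iqr` (q1, q3), `histogram` (tibble
#'   `bin`, `lower`, `upper`, `count`, `proportion`) and
#'   `first_month_prop`.
#' @export
summarize_tto <- function(x) {
  x <- as_onset_vector(x)
  if (!length(x)) abort("no onset records to summarize")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  k <- max(1L, ceiling(max(x) / 30))
  breaks <- c(0, 30 * seq_len(k))
  idx <- cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  counts <- tabulate(idx, nbins = k)
  hist <- tibble(
    bin = seq_len(k),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = counts,
    proportion = counts / length(x)
  )
  list(
    n = length(x),
    median = q[2],
    iqr = c(q1 = q[1], q3 = q[3]),
    histogram = hist,
    first_month_prop = hist$proportion[1]
  )
}

weibull_negloglik <- function(theta, x, lx) {
  alpha <- exp(theta[1])
  beta <- exp(theta[2])
  n <- length(x)
  -(n * log(beta) - n * beta * log(alpha) + (beta - 1) * sum(lx) -
      sum((x / alpha)^beta))
}

#' Fit a two-parameter Weibull to onset times by maximum likelihood
#'
#' Optimizes the likelihood over (log alpha, log beta) with BFGS; the
#' Hessian at the optimum gives Wald confidence intervals on the log scale,
#' back-transformed so the bounds respect positivity. Onset times of
#' exactly zero (event on the start date) are shifted to 0.5 days before
#' fitting, since the Weibull support is positive; the shifted count is
#' reported. The fit is deterministic for fixed input.
#'
#' @param x Onset days (vector, records tibble, or [compute_tto()] result).
#' @param conf Confidence level for the Wald intervals (default 0.95).
#' @return A `weibull_fit` with `alpha` (scale, days), `beta` (shape),
#'   `alpha_ci`, `beta_ci`, `n`, `n_zero_shifted`, `loglik` and
#'   `failure_type` (see [classify_failure_type()]).
#' @export
#' @examples
#' fit_weibull(generate_tto_sample(2000, scale = 300, shape = 0.54, seed = 1))
fit_weibull <- function(x, conf = 0.95) {
  x <- as_onset_vector(x)
  if (length(x) < 2) abort("at least 2 onset records are required")
  n_zero <- sum(x == 0)
  x[x == 0] <- 0.5
  if (length(unique(x)) < 2) {
    abort("degenerate input: all onset values identical; no Weibull fit")
  }
  lx <- log(x)
  ## moment starts from the log-sample: sd(log X) = (pi/sqrt(6))/beta,
  ## E(log X) = log(alpha) - gamma_E/beta
  beta0 <- min(max((pi / sqrt(6)) / sd(lx), 1e-3), 1e3)
  alpha0 <- exp(mean(lx) + 0.5772156649 / beta0)
  fit <- optim(
    c(log(alpha0), log(beta0)), weibull_negloglik, x = x, lx = lx,
    method = "BFGS", hessian = TRUE, control = list(maxit = 500)
  )
  if (fit$convergence != 0) {
    abort(paste0("Weibull optimizer failed to converge (code ",
                 fit$convergence, ")"))
  }
  vcov <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(vcov) || any(diag(vcov) <= 0)) {
    abort("observed information matrix is singular; no usable CI")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(diag(vcov))
  est <- exp(fit$par)
  ci <- rbind(exp(fit$par - z * se), exp(fit$par + z * se))
  out <- structure(
    list(
      alpha = est[1], beta = est[2],
      alpha_ci = c(low = ci[1, 1], high = ci[2, 1]),
      beta_ci = c(low = ci[1, 2], high = ci[2, 2]),
      n = length(x), n_zero_shifted = n_zero,
      loglik = -fit$value, conf = conf
    ),
    class = "weibull_fit"
  )
  out$failure_type <- classify_failure_type(out)
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d  scale alpha=%.2f (%.2f-%.2f)  shape beta=%.3f (%.3f-%.3f)  %s\n",
    x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type
  ))
  invisible(x)
}

#' Classify the hazard pattern of a Weibull fit
#'
#' `early` when the shape estimate and its whole CI lie below 1 (event rate
#' declining with treatment time); `wear_out` when both lie above 1;
#' `constant` when the CI contains 1; `indeterminate` otherwise (evaluated
#' in that order).
#'
#' @param fit A `weibull_fit` from [fit_weibull()].
#' @return One of `"early"`, `"constant"`, `"wear_out"`, `"indeterminate"`.
#' @export
classify_failure_type <- function(fit) {
  stopifnot(!is.null(fit$beta), !is.null(fit$beta_ci))
  b <- fit$beta
  lo <- fit$beta_ci[["low"]]
  hi <- fit$beta_ci[["high"]]
  if (b < 1 && hi < 1) return("early")
  if (b > 1 && lo > 1) return("wear_out")
  if (lo <= 1 && hi >= 1) return("constant")
  "indeterminate"
}

#' Write the time-to-onset artifacts
#'
#' Emits `tto_summary.json` (n, median, IQR, Weibull parameters with CIs,
#' failure type, exclusion tally) and `tto_histogram.csv` (30-day bins).
#'
#' @param tto Result of [compute_tto()].
#' @param fit A `weibull_fit`, or NULL to fit here.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_tto <- function(tto, fit = NULL, dir = ".") {
  smry <- summarize_tto(tto)
  if (is.null(fit)) fit <- fit_weibull(tto)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(summary = file.path(dir, "tto_summary.json"),
             histogram = file.path(dir, "tto_histogram.csv"))
  jsonlite::write_json(
    list(
      n = smry$n, median = smry$median,
      iqr = as.list(smry$iqr),
      first_month_prop = smry$first_month_prop,
      weibull = list(
        alpha = fit$alpha, alpha_ci = as.list(fit$alpha_ci),
        beta = fit$beta, beta_ci = as.list(fit$beta_ci),
        n = fit$n, n_zero_shifted = fit$n_zero_shifted,
        failure_type = fit$failure_type
      ),
      exclusions = as.list(tto$exclusions %||% c())
    ),
    paths["summary"], auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(smry$histogram, paths["histogram"], progress = FALSE)
  invisible(paths)
}
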