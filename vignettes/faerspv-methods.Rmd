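---
title: "Methods: disproportionality screening and onset modelling of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and onset modelling of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
library(dplyr)
```

faerspv screens spontaneous adverse-event report databases in the FAERS
quarterly-file dialect for drug-event signals. This vignette is the
package's own account of the statistical machinery: what each stage
assumes, which knobs matter, how the numerical corner cases are handled,
and what the synthetic validation data can and cannot show about real
reporting data.

## The data model

A *case* is one safety report: demographics (DEMO), drug entries with role
codes PS/SS/C/I (DRUG), MedDRA-coded events (REAC), outcome codes (OUTC),
therapy episodes (THER) and indications (INDI), joined on PRIMARYID. The
same case can appear in several quarterly releases as revised versions
sharing a CASEID. Deduplication follows the FDA rule: keep the version
with the largest FDA_DT; on a tie, the largest PRIMARYID. Partial FDA
dates (YYYYMM, YYYY) are right-padded with "01" *for comparison only* --
an order is all deduplication needs -- while event and therapy dates that
lack day precision are excluded from onset computation rather than
imputed, because onset is measured in days.

Ages arrive as value/unit pairs (`AGE`, `AGE_COD`); all six FAERS unit
codes are converted to years, a missing unit with age at most 120 is
assumed to be years, and converted ages at or beyond 150 are set missing
as a unit-error guard. Drug names are matched after uppercasing and
punctuation/whitespace normalization only; no ingredient dictionary is
shipped (MedDRA and drug dictionaries are licensed), so synonym lists are
caller-supplied, as is the PT-to-SOC map.

## The four screening statistics

For a target drug and a term (PT, or its primary SOC), the fourfold table
counts `a` (target drug, target term), `b` (target drug, other terms),
`c` (other drugs, target term), `d` (neither), with `N = a+b+c+d`. Two
counting conventions are offered. Under event counting (the default) the
margins count distinct (report, term) pairs, so a report with three PTs
contributes three events; under report counting the margins count
reports. In either convention a term counts at most once per report, and
SOC tables are built by collapsing PTs to their primary SOC *before*
counting, so two PTs of one SOC in one report contribute once. The choice
is exposed as `counting =` because public summaries of large screens mix
the two conventions; event counting matches databases summarized as
"events", report counting matches tables captioned "case reports".

The statistics, with their positivity criteria:

* `ROR = ad/(bc)`, flagged when the 95% CI lower bound exceeds 1 and
  `a >= 3`. CI: `exp(ln ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`.
* `PRR = a(c+d)/(c(a+b))`, flagged when `PRR >= 2`, `chi2 >= 4` and
  `a >= 3`, with `chi2 = (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))` and no
  continuity correction.
* `IC = log2(aN/((a+c)(a+b)))`, flagged when `IC025 > 0`.
* `EBGM = aN/((a+c)(a+b))`, flagged when `EBGM05 > 2`, with
  `EBGM05 = exp(ln EBGM - 1.96·sqrt(1/a+1/b+1/c+1/d))`.

A pair is a *positive signal* only when all four criteria hold. The
intersection rule trades sensitivity for a very low false-positive rate;
the null-calibration simulation below quantifies this.

Two deliberate simplifications need stating. First, `EBGM` here is the
observed-to-expected ratio, not DuMouchel's gamma-Poisson shrinkage
estimator; with that reading `IC = log2(EBGM)` holds as an exact
identity, which the tests verify on every computed row. Second, no
posterior variance is available for a frequentist IC, so `IC025` uses the
delta-method variance `V(IC) = (1/a+1/b+1/c+1/d)/ln(2)^2`; it will not
numerically match a Bayesian BCPNN's credible bound, and downstream
checks rely on the IC point estimate, not the bound. Zero cells are never
continuity-corrected: a statistic undefined at a zero cell simply fails
its criterion, because a 0.5 correction silently reshuffles which pairs
are signals.

```{r screen-demo}
cfg <- synth_config(
  n_reports = 2000, seed = 42,
  planted = list(planted_signal("INSULIN GLARGINE",
                                "Lipodystrophy Acquired", 20))
)
ds <- deduplicate(synth_reports(cfg)$dataset)
scr <- run_screen(ds, "INSULIN GLARGINE", level = "pt")
scr |>
  filter(positive) |>
  select(term, a, ror, ror_low, chi2, ic025, ebgm05)
```

## Time to onset and the Weibull hazard trend

Onset is the day difference between the report's event date and the
*earliest* full-precision therapy start date of the target drug on that
report (treatment initiation); one onset per report, since FAERS carries
one event date per case even when many PTs are listed. Records with
missing or partial dates, or negative differences, are excluded and
tallied by reason -- exclusions are data, not errors. Summaries use
30-day bins (`[0,30]`, `(30,60]`, ...) and type-7 (linearly interpolated)
quantiles for the median and IQR; the quantile rule is pinned because
different conventions move a median by a day or two on small samples.

The two-parameter Weibull is fit by maximum likelihood over
`(log alpha, log beta)` (BFGS, analytic log-likelihood), with Wald CIs
from the observed information on the log scale, back-transformed so the
bounds respect positivity. Onsets of exactly zero days (event on the
start date) sit outside the Weibull support and are shifted to 0.5 days
before fitting, with the shifted count reported. The shape `beta`
classifies the hazard trend: `early` when the estimate and its whole CI
lie below 1 (event rate declining with treatment time), `wear_out` when
both lie above 1, `constant` when the CI contains 1, `indeterminate`
otherwise -- evaluated in that order. Fits are deterministic for fixed
input; degenerate inputs (fewer than two distinct values) raise a
diagnostic rather than returning a spurious fit.

```{r weibull-demo}
fit_weibull(generate_tto_sample(20000, scale = 309.48, shape = 0.54,
                                seed = 7))
```

## Subgroups and sensitivity

Stratum dimensions are sex, age, country and dose. Age bins are
`[0,18)`, `[18,65)`, `[65,85]`, `(85,Inf)`: the conventional 18-65 /
65-85 labels share an endpoint, and the shared year is assigned to the
older bin so the bins partition. Dose strata exact-match the parsed IU
dose of the target drug's primary-suspect entry to 10/20/30/40 IU;
anything else is `other`, because free-text dose fields do not
disambiguate per-injection from daily dose -- the package ranks within
the four named groups and makes no claim beyond them. Rankings are
event-level counts within the stratum, ties broken lexicographically,
and every run asserts the partition property: stratum counts plus
`missing` sum to the overall total.

The sensitivity re-screen drops every case that mentions a listed
co-medication in *any* role (suspect or concomitant), then re-runs the
identical screen; an exclusion list matching nothing reproduces the
primary screen exactly.

## The synthetic generator and what it validates

The generator exists so that every downstream stage is testable against
planted ground truth with no database download. Its defaults emulate the
marginal structure of insulin-glargine reporting: reporter and outcome
mixes and missingness rates follow published FAERS summaries for that
drug (39% missing age, 10% missing sex, US-dominated country mix,
consumer-dominated reporters), therapy starts are uniform over 2015-2023,
and onsets are Weibull with scale 309.48 days and shape 0.54 -- an
early-failure regime. Events are independent per-PT inclusions whose
rates decay over a 30-term vocabulary; planted associations multiply the
per-report inclusion *odds* of one PT for reports whose primary suspect
is the planted drug, so the report-level odds ratio is the planted
multiplier by construction and is recoverable from the truth ledger's
exact cell counts. Duplicates clone a report under the same CASEID with
an FDA_DT bumped by 0-90 days (a zero bump exercises the PRIMARYID
tie-break), a larger PRIMARYID and, half the time, one perturbed event;
because the clone always wins the dedup rule, the truth ledger is
computed from the clone's event set.

Validation sizes are chosen to keep each property sharply testable at
interactive runtimes: the planted-recovery screen uses 20,000 reports
(one planted pair, odds multiplier 20); null calibration pools roughly
6,000 drug-PT pairs from 200 independent 1,500-report screens with all
multipliers at 1; Weibull recovery uses 50,000 draws, where the shape
MLE's standard error (~0.002) makes a ±0.01 recovery check meaningful;
and the first-month onset mass is checked against the closed form
`1 - exp(-(30/309.48)^0.54)` on 100,000 draws.

One property of the statistics shaped the planted design: an
observed-to-expected ratio is bounded above by `1/P(term)`-type
saturation when the background term is very common, so multiplying the
odds of an already-frequent PT by 20 moves EBGM only modestly. The
planted condition therefore uses a lower-frequency background term,
which is also the regime signal detection is for.

What the generator does *not* emulate -- and hence what passing tests do
not establish about real data: drug-name misspellings and trade-name
synonymy (names are exact up to normalization), reporting-year
heterogeneity and secular reporting trends, correlated event syndromes
(PTs are conditionally independent given the drug), informative
missingness, and true MedDRA hierarchy effects (the bundled map is a toy
covering only the generator's vocabulary). Real-file runs depend on the
caller's synonym list and PT-to-SOC map.

## Reproducibility and numerical conventions

Every stochastic entry point takes an explicit seed; identical seed and
configuration give byte-identical generated files and artifacts, which
the pipeline manifest (MD5 digests of inputs and outputs) makes
checkable. Statistics are computed in double precision; the 2-decimal
rounding seen in exported CSVs is display-only. Screen ordering is
deterministic (count descending, then term lexicographic), as are
tie-breaks everywhere a ranking is emitted.
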