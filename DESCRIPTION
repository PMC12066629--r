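Package: faerspv
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for pharmacovigilance screening of FAERS-style spontaneous
    adverse-event report tables: parsing the quarterly '$'-delimited ASCII
    dialect, FDA-rule deduplication on CASEID/FDA_DT/PRIMARYID,
    primary-suspect filtering, MedDRA PT-to-SOC aggregation, four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with chi-squared, the information component, and the
    observed-to-expected EBGM) with an intersection positivity rule, Weibull
    time-to-onset modelling with failure-type classification, subgroup
    rankings, concomitant-drug sensitivity re-screens, and a synthetic
    report generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
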