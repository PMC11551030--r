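Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event reports. Reads quarterly
    "$"-delimited ASCII tables (DEMO, DRUG, REAC, THER, OUTC, INDI),
    deduplicates case versions, matches a target drug by name and role code,
    and builds case-level 2x2 contingency tables per MedDRA preferred term
    (PT) and system organ class (SOC). Computes four disproportionality
    statistics with their community-standard signal criteria - the reporting
    odds ratio (ROR), the proportional reporting ratio (PRR), the Bayesian
    confidence propagation neural network information component (BCPNN IC),
    and the multi-item gamma Poisson shrinker (MGPS EBGM) - together with
    Pearson chi-square / Fisher exact p-values, Bonferroni adjustment, and a
    four-algorithm consensus rule. Includes time-to-onset summaries,
    gender-stratified subgroup analysis with volcano-plot data, Sankey flow
    cross-tabulations, and a fully parameterised synthetic-report generator
    with known ground truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
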