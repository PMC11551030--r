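---
title: "Disproportionality signal detection on spontaneous-report data"
author: "pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
voluntarily submitted case reports linking drugs to suspected adverse
events. They are the primary post-marketing source for detecting safety
signals that pre-approval trials were too small or too short to see, but
they are not a random sample: reporting is incomplete, duplicated, and
biased by indication and by who files the report. Disproportionality
analysis works around the missing denominator by asking whether an event
is reported *relatively* more often with the drug of interest than with
everything else in the database. A disproportion is a signal of an
association, never of causation.

`pvsignal` implements this workflow end to end for a single target drug
(the shipped defaults are tuned to albumin-bound paclitaxel, matched under
its generic and brand names): ingestion of the quarterly "$"-delimited
ASCII tables, deduplication, case-level 2×2 contingency tables per MedDRA
preferred term (PT) and system organ class (SOC), four disproportionality
statistics with their community-standard signal criteria, Bonferroni
correction, time-to-onset summaries, and a gender-stratified subgroup
analysis. A synthetic-report generator with known ground truth makes every
stage testable without the real database.

## Data model and deduplication

A FAERS *case* (caseid) may appear as several *report versions*
(primaryid). All analyses run on deduplicated data: for each caseid the
version with the latest `fda_dt` is kept, ties broken by the largest
numeric primaryid — the standard FDA-recommended rule. The operation is
idempotent, deterministic (output ordered by caseid), and exactly inverts
the duplicate-version injection performed by the synthetic module, which
the test suite verifies field by field.

Target-drug matching is substring-based on `drugname` and `prod_ai` after
lower-casing and whitespace normalization, restricted to configurable role
codes (default `PS`, primary suspect). Substring matching is deliberate:
FAERS drug names are free text carrying dose and formulation suffixes.
Conventional "paclitaxel" does not match any of the four nab-paclitaxel
name patterns.

Dates come in three precisions (YYYY, YYYYMM, YYYYMMDD) and are kept as
partial dates; only full-precision dates take part in time-to-onset
computation.

## The 2×2 table and the four statistics

For an event term, with the case as the counting unit:

|                | event     | no event |
|----------------|-----------|----------|
| target drug    | a         | b        |
| all other drugs| c         | d        |

and n = a+b+c+d. The comparator is the whole background database, the
usual internal-control choice for spontaneous data. At SOC level a case
with several PTs in one SOC counts once.

The four statistics and their signal criteria (the thresholds universally
paired with these algorithms in FAERS studies):

* **ROR** = (a·d)/(b·c), 95% CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
  Signal: a ≥ 3 and lower bound > 1. Tables with a zero cell receive the
  Haldane–Anscombe +0.5 on all four cells, recorded per term; the a ≥ 3
  gate uses the uncorrected count.
* **PRR** = [a/(a+b)] / [c/(c+d)] with the Pearson χ² of the table (no
  Yates correction by default; a flag enables it). Signal: a ≥ 3, PRR ≥ 2,
  χ² ≥ 4.
* **BCPNN IC**: the information component log₂(p₁₁/(p₁·p·₁)) under
  conjugate Beta shrinkage priors centred on independence (margins
  Beta(1,1); joint cell Beta(1, γ−1) with γ tied to the margins). The
  point estimate is log₂ of the ratio of posterior means; the 95% credible
  bound IC025 uses the *exact* posterior cumulants of IC — every cumulant
  of log X for X ~ Beta(α,β) is a polygamma difference
  ψ⁽ʳ⁻¹⁾(α) − ψ⁽ʳ⁻¹⁾(α+β) — combined through a third-order Cornish–Fisher
  quantile. The suite certifies this closed form against a Monte-Carlo
  posterior sampler (independent Beta draws, 100,000 per table) to within
  0.05 bits on a fixed 20-table grid. Shrinkage keeps zero-cell tables
  finite, so no continuity correction is used. Signal: IC025 > 0.
* **MGPS EBGM**: observed counts are Poisson(λ·E) with E = (a+b)(a+c)/n,
  and λ carries the DuMouchel two-component gamma-mixture prior whose five
  hyperparameters are fitted by maximizing the negative-binomial-mixture
  marginal likelihood across all terms in the run. The posterior is again
  a two-component gamma mixture; EBGM = exp(E[ln λ]) and EB05 is the 5th
  posterior percentile found by root search on the mixture CDF (tolerance
  1e-10). Signal: EB05 > 2 and a ≥ 3.

A term is a **consensus signal** when all four criteria hold
simultaneously; conjunction makes the consensus strictly more conservative
than any single criterion, which the null-calibration tests confirm.
`consensus_and_rank()` additionally applies the Bonferroni-adjusted
p-value filter by default (both filters are independent switches, since
either convention appears in practice) and ranks by descending ROR with a
lexicographic tie-break; the default `top_fraction = 0.2` reproduces the
"top 20% of RORs" view of a signal table.

### p-values and multiplicity

Each table gets a two-sided p-value: Pearson χ² when every expected cell
is at least 5, otherwise the two-sided Fisher exact test; the method used
is recorded per term. The Bonferroni correction divides the significance
level α by the number m of tests in the family (per-test threshold α/m,
adjusted p = min(1, m·p)); with α = 0.05 and m = 10 the per-test threshold
is 0.005. The family is the scanned term list of the run; the gender
subgroup forms its own family.

### Numerical notes

* The GPS fit runs `nlminb` on log/logit-transformed hyperparameters from
  a fixed six-point start grid (including the canonical DuMouchel start
  0.2, 0.1, 2, 4, 1/3) at relative tolerance 1e-8, making the fit
  deterministic and order-invariant. Fewer than 20 terms is refused with
  advice to supply a pre-fitted prior.
* On null-heavy data the fitted prior may drive one gamma component toward
  a point mass near λ = 1. That is an admissible maximum-likelihood fit,
  but it makes the posterior for null terms effectively bimodal, and a
  bimodal posterior's 5th percentile can exceed its geometric mean by a
  hair (< 1%). The EB05 ≤ EBGM ordering is therefore guaranteed only when
  one component dominates — in particular for all elevated terms, which
  are the ones the flags act on.
* ROR/PRR are exactly invariant under scaling all four cells; the Bayesian
  statistics shrink less as counts grow, which the property tests assert.

## Time to onset

Onset is the difference in whole days between the event date and the
earliest therapy start among the report's target-drug rows. Reports are
evaluable only when both dates carry full day precision; negative onsets
and onsets above a plausibility cap (default 3,650 days) are excluded, the
usual reading of "unspecified or inaccurate timing". Quartiles use the
linear-interpolation convention (`quantile` type 7, recorded in the
output). Bins are whole-day intervals closed on both ends — 0–30, 31–60,
61–90, 91–180, 181–360, >360 — with same-day onsets in the first bin; the
bins partition the evaluable set exactly.

## Gender subgroup

Within deduplicated target-drug reports of known sex, each term gets the
female-vs-male 2×2 table (a = females with the term, b = females without,
c = males with, d = males without), so the odds ratio reads "reporting
odds in females relative to males". p-values follow the same
Pearson/Fisher rule, adjusted within the subgroup's own family. The
volcano output plots the natural-log ROR (base recorded in the docs)
against −log₁₀ of the raw p-value; the significance flag uses the
*adjusted* p-value plus a minimum-count rule of 3 on the dominant side's
event count (a_f when log ROR > 0, a_m when < 0).

## The synthetic generator

The generator emulates, case by case and independently:

* **Exposure**: Bernoulli(p_target_drug), default 0.1 of a default 50,000
  reports — large enough that a scan is well-powered, small enough that
  the background dominates, as in the real database where the target drug
  is a sliver of all reports.
* **Reactions**: each PT of the vocabulary enters a case independently.
  With background rate q and injected multiplier ρ, an exposed case's
  inclusion odds are q/(1−q)·ρ, so the population reporting odds ratio
  equals ρ *exactly* — the estimand of the recovery tests. Optional
  per-sex multipliers ρ_F/ρ_M replace ρ for exposed female/male cases,
  making the within-drug female-vs-male odds ratio exactly ρ_F/ρ_M. A case
  that draws no PT receives one uniformly-random PT, since a safety report
  must carry at least one event; with the default vocabulary (background
  rates summing to ≈1.5) this fallback fires for roughly a fifth of
  background cases and spreads thinly over 40 PTs, which measurably
  attenuates the empirical ROR of the very rarest injected terms. Recovery
  tests therefore use vocabularies with near-certain filler PTs that make
  the fallback probability negligible (~5·10⁻⁵).
* **Demographics**: categorical draws whose defaults follow the clinical
  profile typical of a nab-paclitaxel reporting population — sex 48.1% F /
  42.13% M, ages concentrated in 18–65 and >65, weight mostly unreported,
  healthcare-professional reporters ≈89%, US-led country mix,
  death/hospitalization-heavy outcomes, pancreatic/breast/lung cancer
  indications. All are configuration, not constants.
* **Onset**: log-normal by default with median 41 days. The target
  quartiles 11 and 97 days are not jointly attainable by any log-normal
  with that median (the log-ratios 41/11 and 97/41 are asymmetric), so the
  default σ is the least-squares fit to both quartiles in log space,
  σ = ln(97/11)/(2·z₀.₇₅) ≈ 1.614, which yields quartiles ≈14 and ≈122 —
  the residual mismatch is inherent and a Weibull option is provided. A
  configurable fraction of exposed cases (default 53.84%, leaving 46.16%
  evaluable) has its event date degraded to month precision. The
  log-normal's heavy tail also places more mass beyond 360 days (~9%)
  than the 3.5% a real reporting profile shows; the binned output reports
  whatever the configured distribution yields.
* **Versions**: `inject_duplicates()` adds 1–2 earlier-dated versions per
  selected case; deduplication provably restores the original collection.

What it does *not* emulate: co-occurrence structure between PTs (inclusion
is conditionally independent given exposure), indication-dependent event
rates (indication bias), co-medication networks, reporting-rate drift over
calendar time, and multi-outcome reports (each synthetic case carries at
most one outcome code). Passing recovery tests therefore demonstrate that
the statistics and pipeline are correct under the stated generative model,
not that real-data signals are unbiased — on real spontaneous data the
same statistics inherit all the reporting biases discussed above.

## Problem sizes used by the test suite

Oracle equivalence runs on a fixed grid of 20 tables spanning a = 3..500
and n ≈ 2·10³..7·10⁵. Coverage uses ~500 generated databases of 20,000
reports; consensus recovery uses 20 databases of 100,000 reports with 5
injected effects (ρ = 8) among 200 null PTs; null calibration uses 10
databases of 50,000 reports. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping a full run in the low
minutes.

## Reproducing a run

```{r, eval = FALSE}
cfg <- run_config(synth = synth_config(n_cases = 50000, seed = 1),
                  out_dir = "pv_run", seed = 1)
bundle <- run_pipeline(cfg)
bundle$top_pt          # ranked consensus signals
bundle$onset           # time-to-onset summary
bundle$gender          # female-vs-male RORs
```

Identical configuration and seed give a bit-identical output bundle; the
manifest records the seed and a hash of the configuration.
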