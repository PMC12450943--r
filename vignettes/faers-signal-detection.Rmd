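---
title: "Disproportionality signal detection for FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect post-marketing reports of suspected adverse drug events.
They have no denominator — no count of patients who took a drug without
incident — so absolute risks cannot be estimated. What can be estimated is
*disproportionality*: whether a particular drug–event pair is reported more
often than the rest of the database would predict. `faersignal` implements
the standard analysis chain for one target drug: ingest the quarterly
ASCII tables, collapse report versions into cases, build drug–event 2×2
contingency tables, apply four disproportionality algorithms with
conventional positivity thresholds, model the time from drug start to
event onset with a Weibull distribution, screen co-reported drug pairs for
interaction signals with the Ω shrinkage measure, and repeat the analysis
within demographic strata and within an indication-restricted subset.

## Data model and cleaning

A FAERS *case* (one patient's report) may appear as several report
versions sharing a `CASEID`. `deduplicate()` keeps, per case, the version
with the latest FDA receipt date, breaking ties by the largest
`PRIMARYID`, and then removes cases named on the quarterly deletion lists.
Two field-handling rules matter downstream:

* **Partial dates.** FAERS dates may carry year, month, or day precision.
  For dedup *ordering* a partial date is completed to the first day of its
  period; for time-to-onset *arithmetic* anything below day precision is
  treated as missing, because onset quartiles of one day only make sense
  with day-resolution subtraction.
* **Age units.** FAERS codes age in decades, years, months, weeks, days or
  hours; `normalize_age()` converts all to years. An unrecognised unit is
  read as years unless that yields an age above 150, which becomes
  missing.

Drug names are normalized by uppercasing, stripping dosage/form suffixes,
and a small static trade↔generic synonym table — deliberately no fuzzy
matching, trading recall for reproducibility. MedDRA itself is licensed
and cannot be shipped; the package bundles a small synthetic PT→SOC map
(`pt_soc_map_synthetic.csv`) with the same interface (`pt`, `soc_name`,
`soc_code`, one primary SOC per PT), and any real map in that shape can be
substituted. Unmapped PTs are excluded from SOC-level tallies but kept at
PT level and listed in a diagnostics attribute, never silently dropped.

## The four disproportionality statistics

For a target drug and event, with `a` reports carrying both, `b` the drug
with other events, `c` other drugs with the event, and `d` neither
(N = a+b+c+d):

* **ROR** = (a·d)/(b·c), interval `exp(log ROR ± 1.96·se)` with
  `se = sqrt(1/a + 1/b + 1/c + 1/d)`; flagged when `a ≥ 3` and the lower
  bound exceeds 1.
* **PRR** = [a/(a+b)] / [c/(c+d)], with the analogous log-scale interval;
  flagged by the MHRA composite rule: `a ≥ 3`, `PRR ≥ 2`, and Yates-
  corrected χ² ≥ 4. Both the corrected and uncorrected χ² are reported;
  the flag uses the corrected value, the convention in the PRR literature.
* **IC** (information component, BCPNN tradition) = log2(a/E) with the
  two-margin expected count E = (a+b)(a+c)/N; flagged when the
  delta-method lower bound IC025 exceeds 0.
* **EBGM** (MGPS tradition) = a·N/((a+b)(a+c)) — the relative reporting
  ratio against the same E — with a one-sided 5% lower bound
  `exp(log EBGM − 1.645·se)`; flagged when `a ≥ 3` and EBGM05 > 2.

A pair is a *signal* when at least one algorithm fires. Note two design
choices. First, the IC and EBGM are implemented in their simplified
observed/expected forms rather than as the full Bayesian BCPNN posterior
or the DuMouchel gamma-mixture shrinkage: the simplified forms make
IC = log2(EBGM) an exact identity and EBGM the plain relative reporting
ratio, which is the internal relationship the package's outputs maintain
and its tests assert; the full empirical-Bayes machinery is an extension
point, not a dependency. Second, when any of b, c, d is zero, the
Haldane–Anscombe 0.5 correction (added to all four cells) is used for the
ROR/PRR intervals only, with point estimates kept on raw counts where
defined; an infinite PRR (c = 0) is reported without an interval.

No multiple-testing adjustment is applied — conventional in this
literature, where signals are screening hypotheses, not confirmations —
but the scan output includes every term evaluated so users can
post-filter. All cell arithmetic is done in double precision; the cross
products overflow 32-bit integers at database scale.

## Time-to-onset and the Weibull model

TTO is the whole-day interval from the earliest start date of the target
drug's therapy records to the report's event date; negative intervals and
sub-day-precision dates are excluded and tallied. Onset is binned into the
conventional windows (0–30 … >360 days) with percentages against both the
TTO-known denominator and the all-reports denominator — the two
denominators answer different questions and both are reported.

`fit_weibull()` maximises the two-parameter Weibull likelihood on the
log-parameter scale (Nelder–Mead, analytic-free), with 95% intervals from
the inverse observed information by the delta method. Same-day onsets are
legitimate data but sit where the Weibull density is singular for shape
< 1, so zeros are shifted to 0.5 day *inside the likelihood only*;
reported records keep their zeros. The hazard classification follows the
shape CI: entirely below 1 is *early failure* (decreasing hazard — events
concentrate shortly after drug start), entirely above 1 *wear-out*, and a
CI containing 1 *random* (the exponential special case).

One calibration subtlety, measured during development and worth knowing:
rounding onset times to whole days biases the shape MLE upward by roughly
0.01–0.015 at shape 0.6 and n ≈ 2000, because rounding moves the
probability mass near zero where the density is steep. That bias is small
against the sampling error of a single fit but large enough to spoil the
*coverage* of the 95% CI across many replicates. The package's replicated
coverage checks therefore run on continuous Weibull draws — coverage is a
calibration property of the estimator — while single-fit recovery checks
use day-rounded data, matching what date arithmetic actually yields.

## The Ω shrinkage interaction screen

For a drug pair and event, with N11 the co-reports carrying both drugs and
the event, N1· the reports carrying both drugs, N·1 the reports carrying
the event, and N the reports in scope:

* E11 = N1·×N·1 / N,
* Ω = log2((N11 + α)/(E11 + α)) with shrinkage constant α = 0.5,
* 95% CI = Ω ± 1.96·SE with SE = 1/(ln 2·√N11),

and the signal is significant when the CI's lower bound exceeds zero. Two
points are deliberate. This E11 is the *two-margin* independence product —
not the Norén three-margin interaction baseline that subtracts the
single-drug effects — so Ω here asks "is this pair-plus-event combination
over-reported?", not "is it over-reported beyond what either drug alone
explains?". And the SE form above is the one consistent with a
shrunk-log2-count statistic whose variance is dominated by the Poisson
noise in N11. The target drug is matched as primary suspect; the co-drug
in any role, since co-medications are rarely the suspect drug. No minimum
N11 is imposed; counts are always attached so sparse pairs read as
exploratory.

## The synthetic cohort generator

Every stage is testable without downloading FAERS because
`generate_cohort()` produces dialect-exact quarterly tables with a
ground-truth manifest. Per case it samples demographics, a drug set
(independent Bernoulli per catalog drug, at least one drug per report),
and events (independent Bernoulli per event given the drug set: baseline
probability times any injected multipliers). Reports with no sampled event
are redrawn wholesale — rejection sampling — so that each case's *relative*
event rates, and hence the injected reporting-rate multipliers, survive
the every-report-has-a-reaction constraint. Duplicate report versions
(1–3 per selected case, always with smaller primaryids and earlier-or-tied
receipt dates, so the true version must win under the retention rule) and
a deletion list are layered on top.

Defaults are fixed once and describe the reporting environment the
bundled analyses assume: sex 75.60% female, the published age, reporter,
report-year, and outcome distributions of a modern biologic's FAERS
cohort; a 2017–2025 reporting window; onset times Weibull(shape 0.60,
scale 161.14 days) with ~13% of target-drug reports carrying
day-resolution dates; 80% of target-drug reports indicated for rheumatoid
arthritis; a 10% duplicate rate and 2% deletion rate. The default catalog
(8 drugs, 20 events with baselines from 0.003 to 0.10) and cohort size
(20,000 cases) are the package's own choice of a desk-scale cohort large
enough for stable counts on mid-frequency events.

What the generator does *not* emulate: drug co-prescription correlation
(drug use is independent across the catalog), event–event dependence,
secular reporting trends, free-text fields, duplicate reports whose field
values drift between versions, and the real MedDRA hierarchy beyond a
PT→SOC map. Passing tests on synthetic data therefore demonstrate
algorithmic correctness and calibration under a known model — not
robustness to the messiness of real spontaneous reports.

## Orchestrated analyses and their conventions

`run_overall()` chains dedup → demographics → PT- and SOC-level scans →
TTO modelling → optional DDI screen, logging counts at each stage, and is
deterministic given inputs and configuration. `run_stratified()` restricts
the whole 2×2 background to each stratum's reports (the standard choice;
a global background would mix stratum reporting cultures into the
comparator). Strata follow the conventional axes: sex; age 18–44, 45–64,
≥65 (computed from normalized age in years, left-closed intervals;
under-18 and unknown excluded); reporter type, where *healthcare
professional* aggregates physician and other-health-professional,
pharmacist stands alone, and unknown is excluded. Strata with no
target-drug reports yield an empty table with a warning; thin strata are
flagged sparse rather than suppressed.

`run_indication_sensitivity()` keeps the full comparator background but
restricts the *target-drug* reports to those whose indication record —
linked to the target drug's own entries — matches the configured
indication. Restricting the background as well would discard the
comparator population wholesale whenever indications are recorded only
for suspect drugs, which is typical. The comparison output reports
positive-PT counts, their overlap, per-PT ROR deltas, and onset medians
in both sets.

Onset summaries are reported two ways on purpose: the quartile summary of
the TTO-known records, and the bin percentages against all reports. When a
published source prints conflicting onset medians for the same record
count, the quartile summary of the known-onset records is the definition
this package follows, and both views are surfaced so the discrepancy is
visible rather than resolved silently.

## Problem sizes and numerical choices

The bundled test suite exercises: exact closed-form checks and a
1,000-table brute-force oracle for the four statistics (agreement to
1e-12 relative); Weibull recovery at n = 1,951 with 200-replicate
coverage on continuous draws; null calibration of the any-method rule and
of the Ω screen across 100 seeded cohorts of 1,000–1,200 cases (the
documented ceiling for the any-method false-positive share of terms is
10%, dominated by the BCPNN flag, which carries no minimum-count gate);
and multiplier recovery at 50,000 cases. These sizes were chosen as the
smallest at which the binomial noise floor sits comfortably inside the
asserted bounds. Optimisation uses Nelder–Mead with a 1e-12 relative
tolerance; ranking ties break alphabetically by term so output order is
total and stable.

## Limitations

Disproportionality is hypothesis-generating: reporting odds ratios are
not risk ratios, and signals here carry no causal weight. The simplified
IC/EBGM forms shrink nothing at small counts (the `a ≥ 3` gates do that
work instead). The Ω screen inherits the two-margin baseline's inability
to separate pair effects from single-drug effects. And the synthetic
generator's independence assumptions make it a correctness instrument,
not a realism benchmark.
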