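---
title: "Methods: monthly trend and misreporting analysis of stent adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monthly trend and misreporting analysis of stent adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentwatch)
```

## The problem

The FDA's MAUDE database collects adverse-event reports for medical
devices as pipe-delimited flat files: a master file (one row per report:
outcome classification and dates), a device file (product codes, brands,
manufacturers) and a narrative file (free-text blocks), joined on a report
key. For coronary stents, three product codes identify the device classes:
`MAF` (bare-metal, BMS), `NIQ` (drug-eluting, DES) and `PNY`
(bioresorbable, BVS).

stentwatch answers three surveillance questions about such an extract:

1. How are reports distributed over device classes and outcomes
   (death / injury / malfunction)?
2. How do monthly report counts trend over a study window, per
   class × outcome?
3. How often does a narrative that plainly describes a patient death sit
   under an injury or malfunction classification (the *misreporting rate*)?

## Cohort construction

**Study window.** The default window is 2011-01-01 to 2020-02-29
(110 months), ending before pandemic-era reporting artefacts. The window is
a configuration value; an analysis extending through March 2020 only needs
`window = as.Date(c("2011-01-01", "2020-03-31"))`.

**Outcome mapping** is total: `D` → DEATH, `I`/`IN`/`IL` → INJURY,
`M` → MALFUNCTION, `O` → OTHER, everything else (including `*` and blanks)
→ UNKNOWN. Only death, injury and malfunction enter the cohort; OTHER and
UNKNOWN are excluded as too sparse and too ill-defined to analyse.

**Event date, not report date.** Binning uses the date the adverse event
occurred. Reporting lag varies by manufacturer; using the received date
would mix reporting behaviour into the clinical signal. Reports without a
parseable event date are excluded (and counted).

**Class expansion.** A report naming devices of two classes yields one
event per class. The alternative — dropping or arbitrating multi-class
reports — would break the additivity of the class-by-outcome table; the
expansion is logged so the choice is auditable.

**Deduplication.** Among same-key reports the latest received date wins
(late reports are typically amendments; ties keep the first encountered).
Reports identical in every field except the key collapse to one, covering
manufacturer resubmissions. Both removals are counted.

**The exclusion log.** Every excluded unit lands in exactly one counter
(`non_target_product`, `unknown_outcome`, `other_outcome`,
`missing_event_date`, `out_of_window`, plus the upstream `duplicate`
count). Counting one unit per (report, matched class) pair — classless
reports count one unit — the identity

> units in = events out + sum of exclusion counters

holds exactly on every run, and is property-tested on randomly contaminated
synthetic datasets.

**Narrative normalization** happens once, at cohort construction: blocks
are concatenated in text-key order with a single space (so no phrase can
match across block boundaries), uppercased, and whitespace-collapsed. All
downstream matching operates on this normalized blob.

## Monthly trends

Counts are binned per calendar month of the window into zero-filled series:
months without reports appear with count 0, because omitting them would
bias slopes toward whatever months happen to have reports. `x` is the
0-based month index (origin = the window's first month; the origin choice
shifts only the intercept, never the slope or correlation).

Each class × outcome series gets an ordinary least squares fit
`y = β₁x + β₀` (β₀ in cases, β₁ in cases/month) and the Pearson correlation
of (x, y) as the strength-of-trend measure. The regression is on monthly
*counts*: the series' intercepts are then directly comparable to the
published monthly trend equations, whose intercepts are consistent with the
published totals divided over the 110 months. A constant series has
slope 0 and an *undefined* correlation, reported as `NA` rather than 0 so
no trend is fabricated. Series with fewer than 3 points are refused as
underdetermined. The pipeline fits all class × outcome series and leaves
judging weak fits to the reader — the reported `R` flags them.

Two comparison statistics summarise cross-class behaviour:
`slope_to_intercept_ratio` (β₁/β₀, the relative monthly change; undefined
at β₀ = 0) and `magnitude_ratio` (|β₁ᵃ|/|β₁ᵇ|, e.g. how many times faster
DES malfunctions grow than BMS malfunctions decline; undefined at zero
denominator slope).

Share percentages are carried at full precision and only rounded for
display (half-away-from-zero; 3 significant digits for shares, 2 decimals
for rates, matching surveillance-table convention). An empty table has
undefined — not zero — percentages.

## Misreporting analysis

A narrative is a *death-phrase narrative* when it contains, as a contiguous
substring of the normalized blob, at least one of seven fixed phrases
(`death_terms()`). Fixed-string matching after normalization was chosen
over tokenization or stemming deliberately: MAUDE narratives are
conventionally upper-case free text, and substring semantics make the
false-positive surface auditable (the test suite includes a near-miss
suite: "PATIENT EXPERIENCED", "DECENT", "HAD EXPIRED", "PATIENT DIETED"
must never match). A report matching several phrases counts once — the
statistic tallies reports, not matches. Negation handling and statistical
NLP are out of scope.

Per event-date year and per scope (each class and their combination):

- *total* = death-phrase narratives classified death, injury or malfunction;
- *misreport* = death-phrase narratives classified injury or malfunction;
- *rate* = 100 · misreport / total (undefined, not 0, for empty cells).

The denominator is the death-phrase narrative count across all three
cohort classifications — the operational reading of a totals-based
definition; both counts are emitted so either convention can be formed
from the table. BVS is computed on request but excluded from the default
scopes: with well under 1000 reports over a decade its yearly cells are
too small for a stable rate. Calendar years only partially covered by the
window (e.g. a February window end) are emitted but flagged `partial`.
Each class's share of combined misreports (`misreport_share_by_class`) is
computed against the combined misreport total.

## The synthetic-data generator

`generator_config()` + `generate_dataset()` define the study conditions the
package is validated under; they emulate the structure of a real extract,
not its full texture.

- **Monthly intensities.** Counts per class × outcome × month are drawn
  with mean `μ(x) = max(0, β₀ + β₁x)` — Poisson by default, negative
  binomial with variance `dispersion · μ` on request, because real MAUDE
  series are noisier than Poisson: at these means pure Poisson noise gives
  |R| values higher than real extracts show. The default trends use the two
  published malfunction equations verbatim (BMS `β₀ = 51.7, β₁ = -0.38`;
  DES `β₀ = 190.1, β₁ = 1.5`); the remaining series have no published
  equations, so their intercepts are set to match the published
  class-by-outcome totals spread over 110 months, with slopes encoding the
  described behaviour (DES injuries mirror DES malfunctions at `-1.5`;
  BMS injuries decline gently; deaths decline slightly; the small BVS
  series are flat — the real BVS series peaked mid-window, a shape a linear
  generator deliberately does not model).
- **Misclassification mechanism.** Each death-mechanism report is
  classified DEATH with probability 1−ρ and uniformly INJURY or MALFUNCTION
  with probability ρ — the report-level classification flip that the
  misreporting statistic estimates. Its narrative contains exactly one
  uniformly chosen death phrase with probability `death_term_frequency`;
  non-death-mechanism narratives never contain one, verified against the
  matcher at generation time. Defaults are the published study conditions:
  ρ = 0.1676 (BMS), 0.0568 (DES), the 7.01% combined rate for BVS, and
  `death_term_frequency = 0.66`, the published ratio of death-phrase
  narratives to death classifications. Because phrase presence is
  independent of the flip, the tabulated rate is an unbiased estimate of ρ,
  and conditional on the death-phrase count n the misreport count is
  exactly Binomial(n, ρ) — the basis of the coverage test
  (ρ ∈ {0.05, 0.10, 0.25}, 100 seeded replicates each, ≥500 death-phrase
  narratives per replicate, ≥93 replicates inside the exact central 95%
  binomial interval).
- **Contamination** injects *additional* rows — full-content duplicates
  under fresh keys, rows with missing dates, unknown/other outcome tokens,
  or non-stent product codes — so clean ground-truth counts are preserved
  and every injected row is either removed by deduplication or lands in
  exactly one exclusion counter, which the accounting-identity tests
  exploit. Every narrative embeds its report's reference id, so distinct
  clean reports can never be full-field identical by chance and
  deduplication removes exactly the injected duplicates.
- **Determinism.** One seed fixes the dataset bit-for-bit (files included);
  changing only the seed changes realizations, never the configuration
  echo. Injury tokens are emitted as a mix of `I`/`IN`/`IL`, dates in both
  accepted dialects, and one in five narratives is split across two text
  rows, so the reader's edge cases are exercised by every generated
  dataset.

What passing tests on synthetic data do **not** show: the generator has no
reporting lags, no seasonal or changepoint structure, no realistic
narrative language beyond phrase placement and near-miss fillers, and no
BVS mid-window peak. Agreement with ground truth validates the *machinery*
(parsing, joining, exclusion accounting, binning, OLS, matching), not any
clinical claim about real stents.

## Numerical and degenerate-input choices

- OLS is solved by `stats::lm`; the test suite cross-checks it against an
  independent normal-equations implementation to |Δ| < 1e−10 on series up
  to 200 points.
- Date parsing is total: both `MM/DD/YYYY` and `YYYYMMDD` are
  auto-detected, impossible calendar days map to missing with a warning,
  never an error.
- Malformed flat-file rows are skipped and counted by default (lenient
  mode, mirroring how a silent-exclusion analysis treats bad records);
  strict mode aborts with the offending line number. Orphan device or
  narrative rows are dropped and counted, never fatal.
- Ratios with zero denominators (empty cohorts, zero intercepts, zero
  slopes, empty misreport totals) are *undefined* (`NA` or an error, per
  contract) — never silently 0.
- Display rounding is half-away-from-zero; all stored values keep full
  precision.

## Problem sizes

The test suite validates on 24-month windows with intensities a few tens
of cases per month (a few thousand reports per dataset), the slope-recovery
studies use 200 replicates of 110-month Poisson series at the published
coefficients, and the misreporting coverage study uses 100 replicates per
rate with roughly 650 death-phrase narratives each. A full default-scale
dataset (~69,000 reports over 110 months) generates and analyses in well
under a minute and is exercised in the README's worked example.

## Limitations

Linear trends only: no changepoint or joinpoint detection, no seasonal
decomposition, no forecasting. No fuzzy record linkage or
manufacturer-name harmonization in deduplication. Phrase matching is
surface-level by design; a narrative can describe a death in words outside
the seven phrases and will not be counted. Real-extract grand totals and
correlation values depend on the actual MAUDE data and are not
reproducible from synthetic conditions; the package validates the method,
and applies it to whatever extract it is given.
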