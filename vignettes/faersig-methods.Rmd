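---
title: "Signal mining for spontaneous adverse-event reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal mining for spontaneous adverse-event reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersig)
```

## The problem

Spontaneous-reporting systems accumulate voluntarily submitted adverse
drug reaction (ADR) reports. They support *disproportionality
analysis* — asking whether a drug–event pair is reported more often
than the database's margins predict — but not incidence estimation:
there is no denominator of exposed patients, reporting is selective,
and a case may be submitted several times as versions accumulate.
`faersig` packages the full workflow for FAERS-style quarterly data:
ingestion of the `$`-delimited ASCII tables, case-level cleaning,
report-level 2×2 tables, four signal statistics with conventional
thresholds, Weibull time-to-onset (TTO) modelling, and cohort summary
tables. A deterministic synthetic-data generator with a ground-truth
manifest makes every stage testable offline.

## Cleaning model

**De-duplication.** The unit of analysis is the case, not the report
version. For each `caseid` the version with the latest FDA receipt date
is retained; ties break toward the greatest `primaryid` (numeric when
ids are numeric). This rule is deterministic and permutation-invariant,
which the tests check by shuffling inputs. Cases listed in the
deleted-case file are then removed.

**Cohort definition.** Target reports are those with at least one
primary-suspect (`PS`) drug row whose product text contains a brand
name from the drug dictionary as a whole word, case-insensitively.
Generic substance names are deliberately not in the dictionary:
substance-level retrieval would pull in non-ophthalmic use of the same
molecules. A report naming two different target brands as `PS` is
assigned to both drugs — per-drug report counts stay additive and no
report is silently dropped. Reports with no matching `PS` row are kept
as the comparator arm, so the 2×2 reference set is the whole retained
corpus.

**Normalization.** Ages are converted to years (decades ×10, months
/12, weeks /52.1775, days /365.25, hours /8766; a missing unit is
taken as years, the dominant FAERS convention), weights to kg. Reporter
occupations collapse to healthcare professional (`MD`, `PH`, `OT`)
versus non-healthcare professional (`CN`, `LW`). Partial dates
(`YYYYMM`, `YYYY`) are retained at parse time with a precision marker;
each downstream stage applies its own requirement — de-duplication
orders partial receipt dates by zero-padding, while TTO demands full
8-digit precision on both dates.

## Disproportionality statistics

For a drug–term pair, each retained report falls in exactly one cell of
the 2×2 table (`a`, `b`, `c`, `d`; `N = a+b+c+d` equals the retained
corpus size — an invariant the tests recount by brute force). The four
statistics and thresholds are the conventional ones:

* **ROR** `= ad/bc`; Wald interval on the log scale with
  `SE = sqrt(1/a+1/b+1/c+1/d)`; signal when `a ≥ 3` and the lower 95%
  bound exceeds 1. The ROR is the primary method; the others corroborate.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with
  `SE = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`; same gate. Algebraically
  `|ln ROR| ≥ |ln PRR|` and both deviate from 1 in the same direction,
  properties the suite checks over random tables.
* **BCPNN.** Raw information component
  `IC = log2(aN/((a+b)(a+c)))`; the Bayesian version shrinks it using
  Dirichlet priors with hyperparameters `γ11 = α1 = β1 = 1`,
  `α = β = 2`, and joint prior weight
  `γ = γ11 (N+α)(N+β) / ((a+b+α1)(a+c+β1))`. The signal statistic is
  `IC025 = E(IC) − 2√V(IC) > 0`.
* **EBGM.** Implemented exactly as the simplified closed form
  `aN/((a+b)(a+c))` — the relative reporting ratio, identical to
  `2^IC` — with log-normal 95% bounds and the `EBGM05 > 2` gate. This
  is *not* a full gamma-Poisson (MGPS) posterior; with that model out
  of scope, the closed form is documented prominently so users do not
  read shrinkage into it.

**A calibration subtlety worth stating.** The prior weight `γ` above
calibrates the posterior expectation `E(IC)` to zero on an *empty*
table, not under per-table independence: when `a = (a+b)(a+c)/N`,
`E(IC) = 0` holds exactly only if both margins equal `N/2` (for
example any balanced table `(k,k,k,k)`), and otherwise only
asymptotically — for `(10, 90, 90, 810)` the value is `−0.0209`,
vanishing as counts grow. The acceptance suite records this: the
exact-zero expectation on unbalanced independence tables fails by that
small margin, while the balanced-table identity and the convergence of
`IC025` to the raw `IC` under count scaling hold.

**Zero cells.** If any of `b`, `c`, `d` is zero, 0.5 is added to all
four cells (Haldane–Anscombe) and the row is marked `corrected`,
keeping intervals finite; the `a ≥ 3` gate always uses the uncorrected
count, and `a = 0` terms are never emitted. **Multiplicity.** No
multiple-testing adjustment is applied; threshold gating is the only
filter, consistent with standard practice for these thresholds. The
combined `all_four` flag is the conjunction of the four per-method
flags; per-method flags are always emitted so ROR-only screening is a
column selection.

## Weibull time-to-onset

Induction time is `event date − therapy start` in days, requiring full
date precision and a strictly positive interval; exclusions are tallied
by reason, never silently dropped. Exact zeros are excluded rather than
jittered: the Weibull support is `t > 0`, and same-day onsets carry no
interval information at day resolution. There is no censoring model — a
spontaneous-reporting system only contains reports where the event
occurred, so the plain uncensored likelihood is the right one.

The fit maximizes the two-parameter Weibull likelihood in
`(log α, log β)` by BFGS from a moment-based start (`log t` is
Gumbel-distributed with `sd = π/(β√6)`), so the optimizer is
deterministic and the log-likelihood at the optimum provably beats the
start (checked). Confidence intervals are Wald on the log-parameters
using the observed information, transformed back — chosen over profile
likelihood for determinism and speed; near-boundary fits (very small
`n`, shapes near 0) are where the two can differ materially, and fits
are refused below 10 distinct values. Quartiles use linear
interpolation at rank `1+(n−1)p` (`quantile` type 7). Hazard
classification follows the shape interval: entirely below 1 → early
failure (decreasing ADR incidence), containing 1 → random failure,
entirely above 1 → wear-out failure.

For the random-failure regime, "classifying correctly" is exactly the
event that the interval covers 1, so the long-run correct-classification
rate equals the interval's coverage probability (≈0.93–0.95 at
`n = 1000`; an independent fitter's intervals behave identically on the
same draws). A fixed demand of ≥95 correct out of 100 replicates
therefore sits on the noise floor; the acceptance suite states it
anyway and the observed 92/100 under the pre-registered seeds is
reported as-is.

## Synthetic-data generator

`sim_config()` describes one synthetic quarter; its defaults are the
package's reference conditions: 5,000 cases; seven target brands with
marginal probabilities 0.08, 0.10, 0.09, 0.05, 0.03, 0.04, 0.02 over a
20-product background pool; 17 preferred terms under a toy hierarchy
(eight ocular terms among them) with background rates averaging ~1.9
reactions per report; one planted association (Ozurdex–Cataract,
relative risk 10) — strong enough for all four thresholds at this size
while leaving every background pair null; per-drug Weibull onset delays
(scales 7.6–255 days, shapes 0.39–0.76, i.e. early-failure regimes);
5% duplicate versions, 1% deleted cases, 5% partial event dates. Every
draw descends from the mandatory seed, and identical configs produce
byte-identical files.

Deliberate simplifications, hence limits on what passing tests show
about real data: reactions are independent Bernoulli draws per term
given the drug (no within-report PT correlation, no syndrome
structure); reports with no drawn reaction receive one forced term from
the background distribution, which is drug-independent — it induces no
spurious association but does add `prod(1−p)·p_i/Σp` to each term's
marginal, which the generator tests account for exactly; co-reported
drugs are unstructured; onset delays are rounded to whole days (redrawn
at zero), which truncates sub-day mass and biases fitted shapes
slightly upward for heavy-near-zero regimes; there is no reporting-lag
or country-specific structure. Real FAERS quarters additionally carry
free-text noise, indication-driven confounding, and duplicate cases
spanning quarters under different caseids, none of which are emulated.

Problem sizes used by the test and acceptance suites — 2×2 recounts on
corpora ≤ 1,000; planted-signal recovery at 5,000; the null
calibration at 200 replicates × 500 reports × 50 terms; Weibull
recovery at 2,000 draws and 100 classification replicates per regime —
were chosen as the smallest sizes at which the binomial/Wald error
bands in play are decisive.

## Open choices resolved

* ASCII quarters (not XML) are the ingestion format; legacy pre-2012
  column names are out of scope.
* Multi-brand `PS` reports are multi-assigned (see above) rather than
  single-assigned; the alternative silently discards signal for one
  drug.
* Outcome tables count outcome occurrences (a report may carry several
  codes, or none → a `Missing` occurrence) and use occurrence totals as
  percentage denominators; all other cohort categories partition
  reports and use report totals. Percentages round half-up to one
  decimal, the convention that reproduces conventionally printed
  tables.
* The intersection of per-drug signal sets is reported as computed —
  no expected count is hard-coded.
* Per-drug TTO uses one time per case: the earliest full-precision
  therapy start among that drug's `PS` rows.

## Limitations

Disproportionality is not risk: these statistics rank reporting
associations within a biased corpus and cannot support incidence or
causality claims. The simplified EBGM lacks true empirical-Bayes
shrinkage and will exceed the MGPS posterior mean for small `a`. The
screening thresholds are conventions, not error-rate guarantees —
although on null synthetic corpora the conjunction of all four flags
has a measured per-term false-flag rate near zero. Real-data use still
requires the user to supply a licensed MedDRA mapping and a curated
brand dictionary.
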