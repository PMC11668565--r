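# faersig

Pharmacovigilance signal mining for FAERS-style spontaneous adverse-event
reports, with ophthalmic corticosteroids as the motivating use case.

Spontaneous-reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect adverse drug reaction (ADR) reports as quarterly
`$`-delimited ASCII tables (DEMO, DRUG, REAC, THER, OUTC). Before any
inference these data need case-level cleaning: one retained version per
case, deleted cases removed, and the analysis restricted to reports in
which a drug of interest was the *primary suspect* (role code `PS`),
retrieved by brand-name search. `faersig` implements that cleaning
pipeline, the four standard disproportionality statistics with their
conventional signal thresholds, Weibull time-to-onset modelling, cohort
characteristic tables, and a fully deterministic synthetic-FAERS
generator so the entire pipeline is testable without any download.

## The statistics

All four methods start from a report-level 2×2 table for a (drug, term)
pair — `a` reports with drug and term, `b` with drug only, `c` with term
only, `d` with neither, `N = a+b+c+d`:

| Method | Estimate | Signal threshold |
|---|---|---|
| ROR | `ad/bc`, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))` | `a ≥ 3` and lower CI > 1 |
| PRR | `[a/(a+b)]/[c/(c+d)]`, CI on the log scale | `a ≥ 3` and lower CI > 1 |
| BCPNN | `IC = log2(aN/((a+b)(a+c)))` with Bayesian shrinkage; `IC025 = E(IC) − 2√V(IC)` | `IC025 > 0` |
| EBGM | simplified closed form `aN/((a+b)(a+c))` with log-normal bounds | `EBGM05 > 2` |

Terms are MedDRA preferred terms (PT) or, via a user-supplied
PT→HLT→HLGT→SOC mapping table, system organ classes (SOC). Licensed
MedDRA content is never shipped; a toy hierarchy (`toy_meddra()`) covers
the synthetic data.

Time to onset (therapy start to event onset, in days) is summarized by
quartiles and a two-parameter Weibull maximum-likelihood fit; the shape
parameter classifies the hazard as *early failure* (β CI below 1,
decreasing ADR incidence), *random failure* (CI containing 1), or
*wear-out failure* (CI above 1).

## Worked example

```r
library(faersig)

# a synthetic quarter with a planted Ozurdex/Cataract association (RR 10)
sim <- simulate_faers(sim_config(seed = 101, n_reports = 5000))
reports <- clean_reports(sim$tables, sim$deleted, sim$dictionary)
reports
#> faers_reports: 4950 retained cases; 2032 with a primary-suspect target drug
#> tgt
#>   Lotemax   Durezol   Ozurdex   Maxidex       FML   Iluvien Triesence
#>       499       454       415       219       196       146       103

print(screen_drug(reports, "Ozurdex"), n = 3)
#> Signal screen: Ozurdex at PT level (4950 reports, 17 terms)
#>                term  a   ror ror_lo95  ic025 ebgm05 all_four
#>            Cataract 81 13.17    9.501  2.064  4.276     TRUE
#>  Device malfunction  7  1.37    0.621 -0.761  0.600    FALSE
#>  Retinal detachment 22  1.30    0.827 -0.342  0.798    FALSE
#> ... 14 more terms
```

The planted pair is the only term flagged by all four methods: its ROR
of 13.2 (lower CI 9.5) means Ozurdex reports name cataract about
thirteen times more often, in odds terms, than reports of all other
drugs in the corpus, and the shrunken lower bounds (IC025 > 0,
EBGM05 > 2) confirm the disproportion survives Bayesian damping.

```r
fit <- fit_weibull(induction_times(reports, "Ozurdex"))
fit
#> Weibull time-to-onset fit (n = 395 )
#>   scale alpha = 35.6611 days (95% CI 30.5876-41.5761)
#>   shape beta  = 0.6805      (95% CI 0.6312-0.7337)
#>   median 17.0 d (IQR 5.0-59.0); early failure
```

A shape below 1 with its whole interval below 1 is the early-failure
pattern: ADR incidence is highest soon after therapy start and declines
thereafter, recovering the regime of the generator's configured onset
distribution (α 32.5, β 0.55 for this drug; dates carry whole-day
precision, and that rounding pulls the fitted shape slightly above the
continuous-time value).

End-to-end, writing every artifact as TSV plus figures:

```r
simulate_faers(sim_config(seed = 101, n_reports = 5000), dir = "quarter")
run_pipeline("quarter", "out")      # signals, TTO, demographics, overlap
plot_outputs("out")                 # heatmap + overlap figure from TSVs
```

A thin CLI wrapper with the same subcommands lives at
`inst/scripts/faers-pipeline.R`. Column orders of all outputs follow the
data frames returned by `screen_drug()`, `tto_summary()`,
`summarize_cohort()` and `common_terms()`.

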