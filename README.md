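# matchdid

Matched difference-in-differences for long-format longitudinal cohorts,
built for the study design behind questions like *"does (re-)entering the
labour market after 65 protect against cognitive decline?"*: biennial
ageing panels (KLoSA/HRS-style) with a bounded integer cognition score
(MMSE-like 0–30 or TICS-like 0–27), a binary employment state, and
confounded selection into employment transitions.

It is aimed at epidemiologists and applied economists who want the
treatment-history matching estimator as a tested, reusable package — plus a
synthetic cohort generator so that every stage of the pipeline can be
exercised and calibrated without restricted survey downloads.

## The estimator

For the *entry* direction, a treated event is a person-wave `(i, t)` moving
from non-employment at `t − 1` to employment at `t`; its matched set
`M_it` contains every control observation at the same wave with an
*identical employment history* over waves `t − L .. t − 1` that stays
non-employed at `t` (symmetrically for *exit*). Matched sets are then
refined by weighting controls with similar pre-treatment covariate
histories — covariate balancing propensity score (CBPS) weighting by
default, with Mahalanobis-distance matching, propensity-score matching and
plain propensity-score weighting as comparators. The effect at lead `F` is
the weighted DID contrast, averaged over treated events with non-empty
matched sets:

```
DID(F, L) = (1/N) Σ_{i,t} [ (Cog_{i,t+F} − Cog_{i,t−1})
                            − Σ_{i′ ∈ M_it} w_it^{i′} (Cog_{i′,t+F} − Cog_{i′,t−1}) ]
```

with `L = 3` lags and leads `F ∈ {0, 1}` by default. Standard errors come
from a weighted block bootstrap: the estimator is decomposed into per-unit
contributions, whole units (their full time series) are resampled with
replacement, and refinement weights stay frozen. Balance and parallel-trend
diagnostics report standardised mean differences (SMD) of every covariate
history feature and of pre-period outcome levels and changes, before and
after refinement.

## Worked example

```r
library(matchdid)

## a synthetic biennial cohort, 2006-2020: entry raises cognition by 0.65
## points at the transition wave, no carry-over, no confounded selection
sc <- scenario_config(n_units = 2000, tau_entry = 0.65, tau_exit = -0.44,
                      confounding_on = FALSE, seed = 7)
cohort <- generate_cohort(sc)

fit <- panel_did(cohort$panel, "entry", reps = 1000, seed = 7)
fit
```

```
Matched difference-in-differences (entry, L = 3, refinement = cbps_weight)
Treated events: 223 matched: 223 unmatched: 0 

 direction F   adjusted estimate    se ci_low ci_high n_treated n_unmatched
     entry 0 unadjusted    0.562 0.157  0.242   0.866       223           0
     entry 0   adjusted    0.896 0.162  0.553   1.212       223           0
     entry 1 unadjusted   -0.498 0.146 -0.769  -0.200       223           0
     entry 1   adjusted   -0.217 0.157 -0.510   0.129       223           0
```

Reading the output: 223 labour-market entries at ages 65+ in the 2012–2018
treatment window survived the consecutive-participation filter and found at
least one history-matched control. The CBPS-adjusted effect at the
transition wave (`F = 0`) is **0.896 score points (95% CI 0.553–1.212)** —
one draw from a data-generating process whose true effect is 0.65, i.e.
within sampling error (the Monte-Carlo mean over 100 such cohorts,
recomputed by `scripts/acceptance.R`, is 0.650). At `F = 1` the adjusted
estimate returns towards the configured carry-over of zero; it is pulled
slightly negative because matched controls may themselves enter the labour
market one wave later. `summary(fit)` adds the exclusion tally and the
balance summary (here max |SMD| drops from 0.463 to 0.154 after CBPS
weighting), `plot(fit)` draws the point-range figure, and
`run_study()` executes both directions plus subgroup splits and writes
Table-2-shaped CSV outputs.

## Package layout

| file | contents |
| --- | --- |
| `R/panel.R` | `cohort_panel` data model, CSV I/O, lag navigation |
| `R/transitions.R` | transition coding, eligibility filters, currency harmonisation |
| `R/covariates.R` | covariate-history matrices: tertiles, one-hot, missingness indicators |
| `R/matching.R` | exact treatment-history matched sets |
| `R/refine.R` | the four refinement methods, CBPS solver |
| `R/estimator.R` | the weighted DID contrast |
| `R/bootstrap.R` | weighted block bootstrap |
| `R/diagnostics.R` | balance and pre-trend SMD tables |
| `R/generate.R`, `R/fixtures.R` | synthetic cohort generator, hand-checkable fixtures |
| `R/panel_did.R`, `R/pipeline.R` | the `panel_did()` front-end, `run_study()`, `simulate_study()` |

The methods vignette (`vignettes/matched-did.Rmd`) documents the model,
its assumptions, the synthetic data-generating process and all numerical
choices.
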