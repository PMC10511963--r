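---
title: "Matched difference-in-differences for late-life employment transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched difference-in-differences for late-life employment transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchdid)
```

## The design

`matchdid` estimates the effect of a binary state change — here, entering
or exiting the labour market between consecutive survey waves — on a
bounded integer outcome such as a global cognition score, in observational
panel data where selection into the transition is confounded.

The design mimics a trial emulation in three stages:

1. **Treatment-history matching.** A treated *entry* event is a person-wave
   `(i, t)` with `employed = 0` at `t − 1` and `1` at `t`; its matched set
   contains every other unit observed at the same wave whose employment
   values over the lag window `t − L .. t − 1` are identical and who stays
   non-employed at `t`. Exit is symmetric. Conditioning on the history
   absorbs unobserved, slow-moving determinants of both employment and the
   outcome (work attachment, job security, health shocks with employment
   consequences).
2. **Refinement.** Within each matched set, controls are re-weighted (or
   pruned) so their *pre-treatment covariate histories* — including the
   lagged outcome itself — resemble the treated unit's. The default is
   covariate balancing propensity score (CBPS) weighting; Mahalanobis
   distance matching, propensity-score matching, and plain
   propensity-score weighting are available as comparators.
3. **DID contrast.** The effect at lead `F` is the average, over treated
   events with non-empty matched sets, of the unit's own outcome change
   from `t − 1` to `t + F` minus the weighted control change over the same
   waves. Differencing removes additive unit-level heterogeneity; the
   matched controls absorb common period effects.

### Identifying assumptions

* **Parallel trends** within matched sets: absent the transition, treated
  and weighted control outcomes would have evolved identically. This is
  untestable at `t`, but its pre-period analogue is checked by
  `pretrend_check()`: SMDs of lagged outcome levels and of lag-to-lag
  changes should be near zero after refinement.
* **Limited carry-over**: the potential outcome may depend on the
  treatment history only through the last `L` waves; `L = 3` (six years in
  a biennial design) is the default, with `L = 2` as a sensitivity
  setting.
* **No interference** between units. The package has no information to
  check this; it is an assumption of the design.

Future treatment paths are deliberately *not* restricted: a matched
control may itself transition at `t + 1`. At `F ≥ 1` the estimand is
therefore the effect of transitioning *at `t`* versus *not at `t`*,
averaged over whatever happens next — the price of keeping matched sets
large enough at longer leads, and the reason lead choices beyond 1 are
discouraged.

## Tunable parameters

| parameter | default | meaning |
| --- | --- | --- |
| `lags` (L) | 3 waves | employment-history length matched exactly; also the covariate-history depth |
| `leads` (F) | 1 wave | largest post-transition wave evaluated |
| `window` | 2012–2018 | calendar years whose transitions are treatable |
| `min_age` | 65 years | minimum age at the transition wave |
| `refinement` | `cbps_weight` | matched-set weighting method |
| `size_match` (J) | 5 | controls kept by matching-type refinements |
| `reps` | 1000 | block-bootstrap replicates |
| `ci_mode` | percentile | 2.5/97.5 percentile interval; `normal` gives the ±1.96·SE asymptotic form |

The default covariate specification measures age, age², sex, education,
partnership, pre-1945 birth cohort and occupation level at the transition
wave, and self-reported health, household income and asset (as within-wave
tertile ranks) plus the lagged outcome at every lag wave. Income and asset
enter as tertiles because they proxy *relative* economic status; the rank
transform also immunises the analysis against skew and against any
monotone currency harmonisation (`harmonise_currency()` provides the
PPP/deflator scaling hook). Partially observed covariates follow the
dummy-adjustment convention: the missing value is set to 0 and a 0/1
observed indicator enters alongside; occupation is carried forward from
the last observed wave because it is stable and frequently missing.

## Numerical choices

**CBPS solver.** The just-identified balance conditions
`mean[(T − π)/(π(1 − π)) · x] = 0` (with `π` the logistic score) are the
exact gradient of the strictly concave criterion
`mean[(2T − 1)η − T e^{−η} − (1 − T) e^{η}]`, so the package solves them
as a concave maximisation: damped Newton with step halving, initialised at
the logistic MLE, in SVD-whitened coordinates so that nearly collinear
histories (age with age², slowly varying lagged covariates) do not destroy
the Newton system. Convergence is declared when the largest absolute mean
moment falls below `1e-8`. When a feature combination separates or
saturates the groups — in practice most often a missingness indicator that
is constant among treated events — the balance system has *no finite
root*: contributions saturate as the score diverges. The solver then
returns the norm-minimising boundary solution with a warning rather than
failing, which matches the behaviour of GMM-based implementations of the
same estimator; the balance table shows what remained unbalanced. Scores
are clamped to `[1e-6, 1 − 1e-6]` before odds weighting.

**Per-set choices.** Weighting refinements give each control weight
proportional to its fitted odds `ê/(1 − ê)`, renormalised within the set;
the score model is fitted once per direction on the pooled treated and
matched-control events (per-set fits would be underdetermined).
Nearest-`J` selections break distance ties by unit id, then event order,
so runs are bit-reproducible. A singular within-lag covariance in the
Mahalanobis refinement falls back to its diagonal with a warning.

**Bootstrap.** The estimator decomposes exactly into per-unit
contributions `c_j` (own changes minus weighted memberships) and `d_j`
(treated event counts), with `Σc_j / Σd_j` equal to the point estimate;
each replicate resamples the units of the analysis sample with
replacement, in canonical sorted-id order, under the supplied seed.
Refinement weights are frozen inside the bootstrap (they are components of
the estimator); `refit = TRUE` refits the score per replicate as an
honesty check. Replicates drawing no treated unit are redrawn and counted.
The default interval is the percentile interval because the replicate
distribution is visibly asymmetric in small treated samples; `normal`
reproduces the asymptotic form.

**Tertiles.** Cut points are the 1/3 and 2/3 quantiles computed per wave
within the event-eligible sample (not pooled across waves), because
relative economic position is a within-period notion. This is
configurable by supplying a pre-transformed column instead.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* the estimator relies on, not
any particular survey's margins: around 2000 units observed at 8 biennial
waves; baseline age uniform on 55–75; employment following a two-state
Markov chain whose retention (0.80 at 65) and entry (0.12 at 65)
probabilities decline with age on the logit scale; education (4 levels)
driving health, income, asset and occupation with noise; and an integer
cognition score built from an education- and health-dependent level, a
unit intercept (SD 2), age-related decline (0.12 points/year at average
health, faster for poor health), an additive treatment effect at the
transition wave, integer rounding and clipping to the instrument range
(0–30 MMSE-like by default, 0–27 TICS-like). Default effects mirror the
magnitudes this design is used to detect: entry +0.65, exit −0.44 points
at `F = 0`, zero carry-over, applied with a plus sign one wave after entry
and a minus sign one wave after exit when `carryover_f1` is nonzero.

Confounded selection (`confounding_on`, scaled by `selection_strength`)
makes both transitions depend on current self-reported health and the
*lagged realised score* — selection on observables that the refinement
must remove. Because the lagged score contains transitory noise, selecting
on it biases unadjusted change scores by regression to the mean (about
−0.55 points at the default strength — the confounding-correction
experiment in the acceptance script). Attrition is absorbing (once out,
always out, emulating panel dropout under a consecutive-participation
rule) at 3% per wave; item missingness hits income, asset, health and
occupation at 5% per item-wave. A `pretrend_violation` switch adds a
latent "treatment-proneness" score to both the transition logits and the
outcome slope, creating exactly the treated-specific pre-trend that
`pretrend_check()` must detect; it is implemented prospectively so the
outcome process never has to be edited retroactively.

What the generator does *not* emulate: real marginal distributions of any
survey, survey weights, proxy interviews, instrument harmonisation across
countries, spillover networks, or non-monotone response patterns. Passing
tests on these cohorts therefore demonstrates the estimator's internal
correctness and calibration under the design's own assumptions, not
robustness to every feature of real data.

## Calibration evidence

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:
exact agreement of matched sets and estimates with literal brute-force
enumerations on small random panels; null calibration and recovery of an
injected 0.65-point effect at `n = 2000` (100–200 cohorts); at least a
halving of confounding bias with CBPS weighting, with the worst-feature
SMD improving in every simulation; bootstrap determinism, exact
decomposition, and 95% CI coverage inside [0.90, 0.98] at `n = 1000` with
500 replicates; and lag-2/lag-3 agreement under the generator's
first-order employment dynamics. Problem sizes were chosen so the whole
suite runs in a few minutes on one CPU while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* At `F ≥ 1` the estimand includes the consequences of subsequent
  transitions (see above); with a transition-attached effect this pulls
  the `F = 1` contrast slightly towards the opposite sign of the effect.
* CBPS refinement weights are pooled-score odds within matched sets; with
  very strong selection a residual bias of order 0.1 points can remain —
  visible in the confounding experiment — because within-set balance is
  enforced only through the pooled score.
* Subgroup runs re-match within the subgroup, so small subgroups can lose
  all matched sets; such cells are reported `NA` with a reason rather
  than failing the run.
* The weighted block bootstrap treats matched-set weights as fixed;
  uncertainty from estimating the refinement model is ignored unless
  `refit = TRUE`.
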