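---
title: "Treatment-switching estimators under the multistate lens: models, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment-switching estimators under the multistate lens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchclone)
```

## The problem and the model

Comparative long-term safety asks whether the instantaneous risk of an
adverse event (AE) differs between initiators of a test drug (TD) and a
comparator drug (CD) over many years of follow-up, during which patients
switch drugs.  The package represents a patient's history as an
illness-death multistate process without recovery: state 0 is exposure to
the initiated drug, state 1 is "switched", and state 2 is the absorbing AE.
Each transition l → j has a cause-specific hazard α_lj(t), whose cumulative
version is estimated nonparametrically by the Nelson–Aalen estimator — at
each observed transition time, the number of l → j transitions divided by
the number of subjects in state l and under observation just prior.

The two estimators under evaluation do not fit this multistate model.
They construct an augmented two-group dataset by cloning and censoring and
then fit an ordinary Cox proportional-hazards model with a single binary
covariate (analysis arm), testing β = 0 with the two-sided Wald test.  The
package's contribution is to make the connection explicit: each approach's
hazard ratio is a ratio of composite hazards,

- hierarchical: numerator P̂_TD(t)·α̂_TD(t) + (1 − P̂_TD(t))·α̂₁₂^CD(·),
  denominator α̂₀₂^CD(t) (CD starters censored at switch);
- overlapping: the symmetric form with P̂_CD(t) and α̂₁₂^TD(·) in the
  denominator as well,

where P̂_TD(t) is the at-risk fraction of TD starters among all records at
risk in the numerator strata at t, evaluated on the analysis timescale of
the chosen variant.  When the clock is restarted for clones, the
switched-stratum hazard enters shifted back to time 0; prevalent-user and
incident-user hazards are then mixed at the same analysis time, which is
harmless only when the hazard is constant.  `transition_curves()` and
`hr_decomposition()` compute exactly these objects, and the tests verify
that the composite cumulative ratio at the horizon tracks exp(β̂) from the
corresponding Cox fit.

## What the synthetic cohorts emulate

`simulate_cohort()` draws, per arm, i.i.d. AE times from a Weibull
distribution in the `rweibull()` parameterization (survival
S(t) = exp(−(t/scale)^shape)), identical in both arms — every study
scenario is a null scenario — and unaffected by switching.  Switching is
assigned at baseline by an independent Bernoulli draw with a common
switching time t*_SW; an assigned switcher whose event precedes t*_SW never
enters the switch state ("theoretical" but not "observed" switcher), which
is why the observed switching proportion falls below the assigned one (30%
assigned gives 30%·S(1) ≈ 23.4% observed in scenario 1).  Follow-up is
administratively censored at 8 years.

The packaged `scenario_table()` carries the 22 study rows: two extreme
scenarios with thousands of events (shape 1/scale 4; shape 0.3/scale 2)
used for the transition-hazard plots, and twenty rare-event scenarios
crossing shape {1, 1.1, 1.2, 1.3, 1.5} (scales calibrated so every scenario
yields ≈330 events) with switching time {1, 5} years and assigned
proportion {25%, 50%}.

What the generator deliberately does **not** emulate: confounding,
covariates, informative censoring, individual (random) switching times,
multiple switches, state-dependent event hazards after a switch, or
competing risks.  Passing tests therefore demonstrate the estimators'
behavior in the idealized setting where switching is the *only*
complication; they say nothing about bias from confounding or informative
adherence in real registry data, and nothing about performance under
alternatives (only parameter-recovery checks use unequal arms, with
switching off).

A note on one of the source descriptions: the extreme constant-hazard
scenario is sometimes glossed as "hazard α = 4", but with scale 4 in the
`rweibull()` convention the event rate is 1/scale = 0.25/year.  The package
follows the rweibull reading throughout: the expected clone count it
implies for scenario 1 (3000·0.3·e^(−0.25) ≈ 701) matches the observed
time-0 clone counts, while a rate of 4 would leave essentially no
switchers alive at 1 year.

## The augmented datasets

Both augmenters emit counting-process records (subject, clone flag,
attributed arm, entry, exit, event, timescale) with half-open at-risk
intervals (entry, exit] and events placed at exit — the standard
convention, matching the risk-set semantics of both the Nelson–Aalen
estimator and the Cox partial likelihood.  Attribution, not current
exposure, defines the arm label.  With `restart_clock = TRUE` all rows are
tagged `"restarted"` and every row enters at 0; with `FALSE` the clone is a
delayed-entry row (s, T] on the original clock, and for the hierarchical
variant each subject's rows exactly partition (0, T] so nobody is at risk
twice at once.  `nelson_aalen()` refuses mixed timescale tags, which would
silently average hazards measured on different clocks.

Two bookkeeping invariants are tested across random cohorts: hierarchical
augmentation conserves total person-time, and the overlapping excess equals
the summed post-switch time of observed switchers.  An observed switch
requires `switch_time < followup_time` strictly (an event exactly at the
switch counts as pre-switch), so zero-length rows cannot arise from the
generator; the augmenters still drop any defensively with a warning, for
imported data.

## Estimation and numerical choices

- **Cox fit**: `survival::coxph()` with Breslow tie handling.  Simulated
  continuous times make ties probability-zero, and Breslow is then
  identical to Efron; the choice matters only for imported data and is
  recorded on the fit object.  `timefix = FALSE` is set because the
  generator produces exact continuous times, including extremely small ones
  under shape < 1 that the default tie-rounding would collapse to
  zero-length intervals.  Degenerate inputs raise classed errors: no
  events, or events confined to one arm (monotone partial likelihood), are
  `fit_error`s, distinct from `convergence_error`s converted from fitter
  warnings.  Tests check the fit against an independent two-stage
  grid search of the Breslow partial log-likelihood to 1e-4.
- **Wald test**: two-sided normal p-value, rejecting strictly below α;
  α = 0.05 throughout, configurable in `run_scenario()`.
- **Nelson–Aalen**: jump times are kept as exact numerics (no
  string round-trips), risk sets honor delayed entry via entry < t ≤ exit,
  and the implementation is cross-checked against `survival::survfit()` on
  left-truncated data.
- **Decomposition grid**: 200 equally spaced points on (0, horizon].
  Mixing uses cumulative-hazard increments over grid intervals weighted by
  the at-risk composition at the interval start (the risk set "just
  prior"), because raw Nelson–Aalen increments are noisy atoms; the
  composite is then directly comparable to cumulative-hazard plots and to
  exp(β̂) via the Nelson–Aalen/Cox correspondence.  Grid points with an
  empty denominator risk set yield `NA`, never a division by zero.
- **Empirical mixture**: with individual switching times the switched
  stratum's marginal hazard is estimated by pooling the individually
  restarted records (0, T_i − t_SW,i] into one Nelson–Aalen estimate.  A
  per-subject nonparametric transition hazard is not estimable, so the
  pooled form is the implemented reading; under the study's common
  switching time it reduces exactly to the shifted single curve, which the
  tests assert.
- **Robust option**: `cox_fit(robust = TRUE)` groups rows by original
  subject across clones for a sandwich standard error — the recommended
  correction when a patient and her clone share risk sets.  It is off by
  default because the study evaluates the approaches as practiced (naive
  fits).  Empirically the clustered se on cloned data is not uniformly
  larger than the naive one, so tests assert its presence and distinctness
  rather than an inequality.

## Reproducibility and the study driver

Every replicate draws from a substream seeded by a deterministic mix of
(base seed, scenario id, replicate index), kept below 2^31.  The same
cohorts are therefore analysed by all four variants, scenarios can be
re-run individually, and `run_study()` output is independent of execution
order.  Replicate-level fit failures are excluded and counted; more than
1% aborts the scenario (none occur in the shipped scenarios, where ≈330
events per cohort keep both arms populated).

Problem sizes: all simulation-based checks run at full cohort size
(3000 + 3000, 8-year horizon).  Replicate counts are the package's choice
per check: 20–25 replicates for event-count and switcher-proportion
calibrations (Monte-Carlo standard errors of a few events), 500 replicates
per scenario for the overlapping deflation bound, 250 replicates per
scenario for the all-scenario nominal-level check of the modified
hierarchical variant (with a Bonferroni-adjusted 99% binomial band across
the 20 scenarios), and 400 for the inflation contrast between the
constant-hazard and the shape-1.5/late-switch scenarios.  The full-scale
figures use `analysis/04_type1_study.R 1000`.

## Known limitations

- Only one switch per patient, in one direction per journey; no
  switch-back, no competing risks, no transition-probability
  (Aalen–Johansen) summaries — cause-specific hazards are the object of
  study, and transition probabilities would mix all three hazards.
- The type-1-error study is exactly that: rejection rates under the null.
  No bias or power surface under alternatives is computed.
- The decomposition's P̂ weights are step functions evaluated on a finite
  grid; with very few events the composite ratio at the horizon is noisy,
  and the 10% agreement tolerance with the Cox fit reflects that.
- Conclusions about the modified (no-restart) variants' validity are
  asymptotic-free empirical statements at the simulated sizes, not proofs.
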