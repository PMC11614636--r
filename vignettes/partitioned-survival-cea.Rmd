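---
title: "A partitioned-survival cost-effectiveness model for first-line immunochemotherapy in advanced gastric cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival cost-effectiveness model for first-line immunochemotherapy in advanced gastric cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceapsm)
```

## The decision problem

Adding the PD-1 inhibitor tislelizumab (200 mg every three weeks) to
first-line platinum/fluoropyrimidine chemotherapy improves overall survival
(OS) and progression-free survival (PFS) in unresectable gastric and
gastroesophageal junction adenocarcinoma, at a substantial drug cost. The
package implements the standard health-economic machinery for asking
whether that trade-off is worth paying for, from two payer perspectives
(China and the United States) and in two populations (the full trial
population and the PD-L1 TAP >= 5% subgroup): a three-state cohort model
driven by parametric survival curves, incremental cost-effectiveness
indices, and a full uncertainty apparatus.

## Model structure

The cohort occupies three health states: progression-free (PFS), progressed
disease (PD) and death. Occupancy is read directly off the two marginal
curves — the *partitioned survival* realization of the three-state model:

* `pfs(t) = min(S_PFS(t), S_OS(t))` (the clamp guards against crossing
  curves),
* `dead(t) = 1 - S_OS(t)`,
* `pd(t)` is the residual.

This is the standard trial-based construction when only marginal OS and PFS
curves are available; an explicit transition-probability formulation would
require data (post-progression survival by time of progression) that
published curves do not carry. Conservation (`pfs + pd + dead = 1`) and
monotone cumulative death hold by construction and are asserted by tests at
every cycle.

The model runs 174 cycles of 21 days — ten years, enough that almost all of
both cohorts has died under every packaged survival configuration.

### Time conventions

Two clocks run in the engine, and their relationship is a deliberate,
configurable choice:

* **Calendar time** advances 21 days per cycle. It drives discounting
  (`(1+r)^(-t_years)`, evaluated at cycle start) and the accrual of QALYs
  and costs (each cycle contributes `21/365.25` years).
* **Survival-curve time** advances `months_per_cycle` months per cycle when
  the monthly-parameterized fitted curves are evaluated. The default is
  `1.0`: one month of curve time per three-week cycle. The packaged
  base-case results are defined under this convention, which matches the
  original decision-analytic implementation of this model class; the strict
  calendar mapping (`21/30.4375 = 0.69` months per cycle) is available by
  setting `months_per_cycle` in the configuration and yields materially
  longer restricted survival (the ten-year horizon then truncates less of
  the heavy log-logistic tails).

No half-cycle correction is applied by default; the
`half_cycle_correction` flag switches continuous accruals to the trapezoid
(adjacent-cycle average), which is also what the closed-form validation
tests use when comparing against continuous-time integrals.

## Survival inputs

Eight parametric families are supported: exponential, gamma, generalized
gamma, Gompertz, Weibull (AFT), Weibull proportional hazards, log-logistic
and log-normal. Conventions that matter:

* The **log-logistic** uses `S(t) = 1/(1 + (t/scale)^shape)`, so `scale` is
  the median — the packaged OS scale (15.14 months, intervention arm,
  intent-to-treat) sits where a first-line trial median should.
* The **generalized gamma** uses the Prentice `(mu, sigma, Q)`
  parameterization, the only convention under which the packaged negative-Q
  PFS parameters are meaningful; the log-normal limit is taken explicitly
  for `|Q| < 1e-6`.
* `weibull_ph` is a reparameterization of `weibull` with identical
  likelihood; it is kept as a separate label because fit reports
  conventionally list both.

`fit_parametric()` maximizes the right-censored log-likelihood with a
multi-start BFGS search on log-transformed positive parameters (relative
tolerance `1e-8`, Nelder-Mead polish). The heavy-tailed three-parameter
families are ill-conditioned, hence several deterministic starting points
(moment-based plus scaled variants, and a grid of `Q` starts for the
generalized gamma). The exponential rate is solved in closed form.
Convergence is always recorded; non-converged fits are excluded from model
selection. `select_best()` is AIC-first with BIC and then parsimony as
tie-breaks. The published analysis additionally used visual inspection of
the fits; that step is not algorithmic and is deliberately not emulated —
selection here is purely information-criterion based, which reproduces the
published choices on the packaged data but need not replicate visual
judgment elsewhere.

## Reconstructing patient data from published curves

`reconstruct_ipd()` rebuilds pseudo individual-patient data from digitized
Kaplan-Meier coordinates plus a number-at-risk table. Within each
inter-risk-time interval the censoring count is solved iteratively so the
implied at-risk count matches the published table (censor times spread
evenly across the interval), and event counts at each digitized drop track
the product-limit estimate. The implementation is deterministic — integer
allocation by rounding, no randomization. Conventions and edge rules:

* At-risk counts are read as *post-event* at each landmark (an event
  exactly at a landmark belongs to the preceding interval);
  `km_estimate()` publishes its risk tables under the same convention, so
  simulate/publish/reconstruct round trips are internally consistent.
* Digitization noise is expected: small non-monotonicities are repaired by
  isotonic clipping; rises above `1e-3` are rejected as genuinely invalid
  input.
* Survivors past the last coordinate are administratively censored there,
  so reconstructed records always sum to the initial at-risk count.
* When a published total event count is supplied, a final pass rescales the
  event total toward it (latest events flipped to censorings); the packaged
  analyses do not use this step.

Round-trip accuracy (simulate, publish at 3-month risk intervals,
reconstruct, re-estimate) is tested to stay within 0.02 absolute survival
at all risk times for a 300-subject arm.

## Costs and their attribution

All costs are US dollars, accrued per cycle and discounted at cycle start.
The attribution rules — where the published analysis is silent, these are
the package's decisions, all configurable:

* **First-line drugs** apply to PFS occupancy. The platinum/fluoropyrimidine
  doublet stops after six cycles; the oxaliplatin+capecitabine share
  continues capecitabine maintenance until progression; tislelizumab runs
  until progression or its configured stopping time
  (`tislelizumab_max_years`). The packaged China configurations keep
  tislelizumab until progression; the US configurations apply the two-year
  stopping rule — the pairing under which the published incremental costs
  and price thresholds are jointly reproducible.
* **Administration**: one event per on-treatment cycle; a flat per-unit
  cost in China, first-hour plus one additional hour in the US.
* **Monitoring**: laboratory costs accrue for all alive occupancy (not only
  on treatment — progressed patients on active subsequent therapy are
  monitored too, and this attribution reproduces the published totals);
  enhanced-CT costs fire as pulses at the scheduled assessments (every 6
  weeks to week 48, then every 9 weeks) against alive occupancy.
* **Progressed state**: the fraction `p_subsequent` receives the configured
  subsequent regimen (ramucirumab plus paclitaxel by default), the
  remainder best supportive care. The default attribution is
  `per_pd_cycle` — the regimen cost accrues every progressed cycle, which
  is the reading that reproduces the published incremental costs.
  `fixed_duration` (a six-cycle course from progression, capped at PD
  occupancy) and `one_time` (the course charged at progression) are
  provided as scenario alternatives.
* **End of life**: a one-time cost applied to incident deaths.
* **Adverse events**: grade >= 3 events with incidence above 3 percent;
  cost equals incidence times unit cost, charged once in the first cycle
  (the published assumption that all severe AEs happen during cycle one).

Total cost is exactly linear in the unit costs (a property test doubles
every unit cost and expects exactly doubled totals), which is also what
makes the price-threshold solver exact.

## Utilities

PFS utility 0.797 and PD utility 0.577 per year, both sourced from EQ-5D
valuations of advanced gastric cancer populations. AE disutilities are
applied once, in cycle one, scaled by one cycle length in years — a small
decrement (about 0.003 QALYs) consistent with the single-cycle AE cost
assumption.

## Economic indices

`compare_strategies()` computes incremental cost `deltaC`, incremental
QALYs `deltaE`, `ICER = deltaC/deltaE`, and the net-benefit indices
`INHB = deltaE - deltaC/lambda` and `INMB = lambda*deltaE - deltaC`
(`INMB = lambda*INHB` is asserted to `1e-9` as a property). Off the
north-east quadrant the ICER is replaced by a dominance label — a ratio of
savings to losses misleads. Willingness-to-pay defaults: $38,042.49 per
QALY in China (three times 2023 per-capita GDP) and $150,000 in the US.

## Uncertainty apparatus

* **OWSA** (`owsa()`): each parameter to its low and high bound in turn,
  ICER recomputed, entries sorted by span. Bounds come from the packaged
  ranges; where a published range is internally inconsistent with its
  baseline (one BSC cost row and three comparator AE-incidence rows), the
  range is replaced by +/-20 percent of baseline and flagged.
* **PSA** (`psa()`): all parameters drawn jointly — gamma for costs, beta
  for probabilities and utilities, method-of-moments with mean at baseline
  and `sd = (high - low)/3.92` (bounds read as a 95 percent interval,
  which is the natural reading absent published standard errors). Each
  draw re-runs both arms end-to-end; results are reproducible under a
  fixed seed. Survival parameters are held fixed: no ranges or
  distributions are published for them. Where one unit cost appears in
  both arms (e.g. oxaliplatin) it is sampled once and applied to both —
  ranges may carry several configuration paths.
* **CEAC** (`ceac()`): fraction of draws with positive INMB on a lambda
  grid (default 201 points from 0 to twice the threshold).
* **Price simulation** (`price_threshold()`): total cost is affine in the
  tislelizumab unit price, so the price at which the ICER equals lambda is
  solved exactly from two model evaluations and clipped to the searched
  grid ($0-500 per 100 mg for China, $0-2,500 for the US); a bisection
  oracle and an inverse-property test (re-running at the threshold returns
  ICER = lambda within $1) guard the algebra.
* **Scenario analysis** (`scenario_subsequent()`): swaps the subsequent
  regimen in both arms at unchanged proportions and reruns the
  deterministic comparison.

The packaged PSA uses 10,000 draws; at that size the full run (both arms
re-executed per draw) completes in well under five minutes on one CPU, and
the tests run it at full size.

## The synthetic-trial generator

`trial_scenario()` / `simulate_trial()` emulate the data structure the
analysis consumes, so reconstruction, fitting and the engine are testable
with no external data. Defaults describe the study conditions: 500
subjects per arm, log-logistic OS/PFS marginals equal to the packaged
intent-to-treat fits, a 36-month administrative cutoff and exponential
dropout at 1 percent per month — a realistic censoring load for a first-line
trial read out at about three years. Subject-level dependence uses a
Gaussian copula with correlation 0.6 between the PFS and OS uniforms, with
`PFS <= OS` enforced by componentwise minimum: the analysis itself uses
only marginal curves, but subject-level data must be internally coherent.

What the generator does *not* emulate — and therefore what passing
round-trip tests do and do not show about real data: digitization error is
idealized as small Gaussian jitter on the survival coordinates
(`publish_km()`, default sd 0.002) rather than the correlated, locally
biased error of a human-operated digitizer; real trials censor
administratively by accrual date (staggered entry), not at one cutoff; and
no covariates or stratification exist. End-to-end recovery (simulate,
publish, reconstruct, fit all eight families, select) returns the
generating family in at least 80 percent of seeded replicates at
n = 2,000.

## Numerical choices and degenerate inputs

* Optimizer: multi-start BFGS on log-scale positive parameters, reltol
  `1e-8`; all-censored inputs and too-few-events inputs are errors, not
  silent results.
* Likelihoods floor density and survival values at `1e-300` to keep the
  objective finite in the tails.
* Occupancy clamps `pfs` at `S_OS` and `pd` at zero; the invariants are
  then exact.
* `compare_strategies()` with two identical strategies returns an undefined
  ICER and zero net benefit rather than `0/0`.
* Beta sampling variance is capped just below `m(1-m)` so the moment match
  stays feasible for extreme ranges.
* The price-threshold solver reports "no finite threshold" when the
  intervention gains no QALYs rather than extrapolating a negative price.

## Known limitations

* The engine is a cohort model: no individual-level heterogeneity,
  time-varying utilities, or dose/weight-based cost recalculation (the
  packaged per-cycle drug costs are taken as published; body-size rows in
  the source tables are recorded nowhere because they are unused).
* Only two strategies are compared; no multi-way efficiency frontier.
* Where the published analysis left conventions unstated (survival-time
  mapping, subsequent-treatment duration, monitoring attribution,
  per-country tislelizumab stopping), this package fixes defaults that
  jointly reproduce the published results and exposes each as
  configuration; alternative readings are legitimate and change results at
  the several-percent level — that residual ambiguity is exactly why the
  acceptance tolerances on cost-side quantities are +/-10 percent.
* PSA percentages depend on the distributional reading of the published
  ranges (95 percent interval vs hard bounds); only qualitative claims are
  asserted about them.
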