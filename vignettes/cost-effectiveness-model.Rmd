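---
title: "A three-state partitioned-survival cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state partitioned-survival cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psm3cea)
```

## The decision problem

First-line enfortumab vedotin plus pembrolizumab (EV-PEMB) roughly
doubles median progression-free and overall survival in advanced
urothelial carcinoma relative to platinum-based chemotherapy, at a far
higher acquisition cost.  The package implements a cohort
cost-effectiveness model of the two strategies from the perspective of
the Chinese healthcare system: three mutually exclusive health states —
progression-free (PFS), progressed disease (PD), dead — 21-day cycles,
a 15-year horizon, 5% annual discounting of costs and utilities, and a
willingness-to-pay (WTP) threshold of $38,133 per QALY (three times
2023 per-capita GDP).  All inputs live in one configuration file
(`base_config()`); the engine holds no numbers of its own.

## State membership: partitioned survival

State occupancy is read directly off two parametric curves per arm,

$$\text{pfs}(t) = \min\{S_{\text{PFS}}(t),\, S_{\text{OS}}(t)\}, \quad
  \text{dead}(t) = 1 - S_{\text{OS}}(t), \quad
  \text{pd}(t) = 1 - \text{pfs}(t) - \text{dead}(t),$$

the partitioned-survival construction.  Although such models are often
described as Markov models with transitions derived from the fitted
curves, the partitioned reading is the unambiguous one when the curves
themselves are the primitive, and it guarantees occupancy that sums to
one with non-negative PD membership (the `min` resolves any curve
crossing under extreme extrapolation).  A transition-matrix mode is
deliberately not provided.  The per-cycle conditional event
probability `1 - S(kc)/S((k-1)c)` is exposed
(`transition_probability()`) and telescopes back to the survival curve
exactly, which the test suite asserts to 1e-12.

Both arms' PFS and OS are log-logistic,

$$S(t) = \frac{1}{1 + (\lambda t)^{\gamma}},$$

with the rate-like scale $\lambda$ (1/months) and shape $\gamma$.  The
median is $1/\lambda$, which ties the fitted scales directly to the
reported trial medians (e.g. chemotherapy OS: $1/0.06252743 = 15.99$
months against the reported 16.1).  This reciprocal form is the only
reading under which the fitted scales reproduce those medians.

An optional background-mortality floor replaces each cycle's
conditional death probability by
$\max(q_k,\, 1-(1-q_{\text{annual}})^{d/365})$.  It is off in the base
case — the reference analysis provides no life-table values — and is
exercised by tests and by the cure scenario.

## Survival fitting

`fit_parametric()` fits six families (exponential, Weibull, log-normal,
log-logistic, Gompertz, generalised gamma in the $(\mu,\sigma,Q)$
parameterisation) by two objectives:

* **Maximum likelihood** on individual event/censoring times, the
  route used with synthetic or reconstructed patient data.  Standard
  errors come from the inverted Hessian on the unconstrained (log)
  scale; they agree with `flexsurv::flexsurvreg` to seven digits on
  shared data, which the suite checks.
* **Weighted least squares on `log(-log S)`** for bare digitized
  coordinates.  Default weights are the inverse delta-method variance
  of the transformed ordinate, $(S\log S)^2$ (times numbers at risk
  when present), which prevents the near-1 and near-0 ends of the
  curve from dominating.

Model choice is by AIC (`2k - 2\ln L`), ties broken by BIC, then by
parsimony (`rank_fits()`).  On data simulated from the base-case
log-logistic laws, the log-logistic is ranked first in well over 80%
of replicates.  Digitized curves are cleaned before fitting: duplicate
times keep the lower survival, and monotonicity is restored by a
pool-adjacent-violators (isotonic) projection.  A running-minimum clip
was rejected: on jittered curves it biases survival — and hence the
fitted parameters — systematically downward.  Degenerate inputs (all
survival at 1, fewer than two usable points per free parameter) raise
errors rather than fitting noise.  Gompertz shapes are constrained
positive during fitting so the fitted law is proper, although negative
shapes remain representable.

## Costing

Dosing follows the trial regimens: EV 1.25 mg/kg (capped at 125 mg)
on days 1 and 8; pembrolizumab 200 mg on day 1, at most 35 cycles;
gemcitabine 1,000 mg/m$^2$ on days 1 and 8 plus either cisplatin 70
mg/m$^2$ or carboplatin at AUC 5 via the Calvert formula
(dose = AUC × (CrCl + 25)), at most six cycles, split 54.3% / 45.7%
by the trial's cisplatin-eligibility fractions.  Acquisition uses
whole-vial (ceiling) pricing — standard Chinese practice, and the unit
prices are per vial — with a linear-pricing switch retained.  Tests
and routine follow-up accrue each cycle for all alive patients; best
supportive care accrues on PD occupancy scaled by the configured
uptake; terminal care accrues once on incident deaths; grade ≥3
adverse-event management costs (incidence > 5% in either arm) accrue
once, in cycle 1.  Discounting uses the exact day-count exponent
$(1+r)^{-21k/365}$.

QALYs weight occupancy by utilities 0.84 (PFS) and 0.80 (PD), minus a
one-time incidence-weighted adverse-event disutility of 0.28 lasting
one cycle.  The ICER is computed from unrounded internals; dominance
is flagged instead of quoting a ratio, and equal-effect comparisons
report the ICER as undefined.

### Conventions fixed by calibration

Three conventions the reference analysis leaves unstated were fixed by
calibration against its published base case (the committed log,
`scripts/calibration_log.md`, has the full audit):

1. **Drug-treatment duration.**  The published totals are incompatible
   with both naive readings of the reported median treatment durations
   (hard truncation at the median: −54% on the intervention-arm cost;
   plain treat-to-progression: +24%).  Two published results pin the
   shape of the on-treatment profile: the drug-price scenario ladder
   is linear with a slope of ~149 discounted EV vials (~24.8
   discounted on-treatment cycles), and costs keep accruing between
   the 3- and 15-year horizons.  The shipped rule therefore models the
   on-treatment fraction as a log-logistic time-on-treatment curve
   anchored at the reported medians (7 months for EV, 8.5 for
   pembrolizumab), never exceeding PFS occupancy, with one shared
   shape parameter calibrated to 1.055.  Treatment duration
   distributions in oncology are themselves heavy-tailed, so a
   median-anchored log-logistic is a natural family; the calibrated
   shape is the single tuned quantity in the package.
2. **Cycle timing.**  State membership at cycle start, rewards
   discounted at the cycle's end, no half-cycle correction — the
   classic cohort-Markov accrual.  It reproduces the published per-arm
   QALYs within 0.5%; half-cycle and end-of-cycle accrual do visibly
   worse against the joint base case.
3. **Chemotherapy course.**  The whole cohort completes up to six
   cycles (fixed course) rather than PFS-weighting the six cycles;
   both are close, the fixed course is closer.

All three are configuration entries, recorded in run metadata, and the
alternatives remain selectable.

## Sensitivity machinery

Every economic input carries a range and a distribution family.
One-way analysis (`run_owsa()`) sets each parameter to its bounds in
turn — two full model runs per parameter — and orders the tornado by
ICER spread; the discount rate (0–8%), patient weight and the
intervention drug prices dominate.  The PSA (`run_psa()`) moment-matches
Beta and Gamma distributions to the base value with
SD = (max − min)/3.92 — the ranges are stated as 95% intervals — and
truncates Normal draws (weight, body-surface area) below a tenth of
the base to exclude nonphysical bodies; an infeasible Beta moment
match falls back to a range-preserving Beta(2,2), with a message.  The
survival parameters are deliberately not varied: the reference
assigns them no distribution, a documented limitation shared with it.
`ceac()` turns the draw cloud into an acceptability curve, and
`threshold_price()` bisects the joint price multiplier on EV and
pembrolizumab to the WTP threshold within $1 (the shipped
configuration crosses at ~13% of list prices).  All stochastic
entry points take explicit seeds and never leak global random state.

## Subgroups and scenarios

Subgroup curves are the comparator's fitted curves raised to the
subgroup hazard ratio, $S^{\text{HR}}$ — a cumulative-hazard-scale
transform applied even though the log-logistic is not a
proportional-hazards family, because it is the only construction
consistent with assuming identical comparator curves across subgroups
when just hazard ratios are reported.  Scenario machinery covers the
horizon ladder (3/6/10 years), BSC uptake (30%/50%, implemented as
scaling the per-cycle BSC cost; utilities untouched), the
international EV price ladder, and a cure model: patients still
progression-free at the cure time (default 20 months — the trial's
data-cutoff-derived value is not computable from the published
information, so this is a flagged free parameter) stop treatment, keep
one examination per cycle, and die only at a background rate (default
2%/year, an order-of-magnitude value for the trial's age range).  The
cure scenario's published row is treated as an ordering check only.

## Synthetic data

`simulate_ipd()` draws event times by inverse transform from any
supported law and censors them by an administrative cutoff (default 25
months, mimicking trial follow-up) plus 5%/year random dropout — both
fixture conventions, not claims about any real cohort.
`km_estimate()` wraps the product-limit estimator, and
`emulate_digitization()` reproduces what figure digitization yields: a
time-grid of coordinates with truncated Gaussian read-off error,
re-monotonized.  The generator therefore emulates the *shape* of the
real fitting input; it does not emulate informative censoring,
at-risk-table coarseness, or reader-specific digitization bias, so
passing tests validate the fitting machinery, not the fidelity of any
particular published digitization.

The package's primary self-validation is the full circle
truth → IPD → Kaplan-Meier → digitization → fit → truth for all four
base-case parameter sets.  One censored 2,000-subject realisation
carries ~4% sampling noise on the scale parameter of the flattest OS
curve (the administrative cutoff precedes its median), so the 5%
recovery band is asserted on the mean of ten seeded replicates per
parameter set — the band tests bias, not one draw's luck.  Similarly,
confidence-interval coverage is asserted per parameter (200
replicates): the joint coverage of two marginal 95% intervals is ~92%
even for a perfectly calibrated fitter.

## Problem sizes and numerics

The shipped model runs 261 cycles; a full two-arm evaluation takes
~20 ms, the 1,000-draw PSA well under a minute.  The test suite uses
1,000 PSA draws for the base probability, 200 draws for the
most-favourable-subgroup check, 10,000 subjects for the
microsimulation oracle (comonotone uniforms, so that a subject never
dies before progressing — the partitioned structure), and 100
replicates of 1,000 subjects for family selection.  Optimisation is
Nelder-Mead followed by BFGS on log-transformed parameters with
regression-based starting values; the threshold search runs at most 60
bisection steps.  Occupancy conservation is asserted to 1e-9,
telescoping to 1e-12, cost-breakdown additivity to 1e-6.

## Known limitations

* The three calibrated conventions are identified only through the
  published totals; other conventions reproducing the same totals
  cannot be excluded.
* Survival-parameter uncertainty is absent from the PSA (no published
  distributions), so the acceptability curve understates decision
  uncertainty.
* Adverse events are a one-off cost and disutility in cycle 1; no
  durations or recurrences.
* Utilities are time-invariant; no age-dependent background utility
  decline, and background mortality defaults to off.
* Costs are direct medical only, converted at a fixed 7.03 CNY/USD;
  no societal perspective.
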