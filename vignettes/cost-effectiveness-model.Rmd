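---
title: "A cohort cost-effectiveness model of early intensive behavioural intervention for autism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort cost-effectiveness model of early intensive behavioural intervention for autism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abacea)
```

## The decision problem

Early intensive applied-behaviour-analysis (ABA) based interventions are
delivered one-to-one to pre-school autistic children for around 30 hours a
week over about two years. They are expensive (about £36,700 per child per
year at 2016/17 UK prices) and are not part of routine UK provision. This
package implements a decision-analytic model asking whether that investment
is cost-effective relative to treatment as usual (TAU, costed as nursery
provision at about £8,600 per year), from two payer perspectives:

* **NHS and social care** (`"nhs_social"`): intervention costs plus social
  care and medical costs;
* **public sector** (`"public_sector"`): additionally the costs of
  education, which differ sharply by school setting.

Benefits are quality-adjusted life years (QALYs); results are incremental
cost-effectiveness ratios (ICERs, incremental cost per incremental QALY),
benchmarked against the £20,000–£30,000 per QALY range used in UK health
funding decisions.

## Model structure

The model is a deterministic cohort model, not a microsimulation: it tracks
the cohort *mean* cognitive ability (ratio IQ) and adaptive behaviour
(Vineland Adaptive Behavior Scales composite, VABS), which drive every
downstream outcome. Cycles are monthly; the childhood horizon is 186 months
(age 3 to 18.5, the average age of leaving secondary education), split into
pre-school (to age 4.5), primary (4.5–11.5) and secondary (11.5–18.5)
phases. Costs and QALYs are discounted at 3.5% per year with a half-cycle
correction (each month's flow is discounted at its midpoint). All flows are
weighted by a survival curve built from a general-population life table
with an autism mortality relative risk applied on the hazard scale;
mortality is identical in both arms.

**Scores.** Under TAU both scores drift linearly at the natural-history
rates (−0.45 VABS and −0.28 IQ points per year). The treated arm adds the
treatment effect to the TAU path: a linear ramp from zero through the
one-year effects (+2.92 VABS, +9.16 IQ) to the two-year effects (+7.00
VABS, +14.13 IQ) at the end of the 24-month treatment. Evidence beyond two
years is essentially absent, so two durability assumptions bracket it:

* *optimistic* — the two-year effect persists to the end of the horizon;
* *pessimistic* — it decays linearly to zero at age 10 (84 model months),
  seven years after baseline.

The within-year path of the effect is not observable from annual
measurements; a linear ramp from zero is the natural choice for a model
that works in mean changes per month.

**Education placement.** At primary entry (month 18) and secondary entry
(month 102) the cohort is split across three settings — mainstream,
mainstream with support, special provision — by an ordered (cumulative)
logit on the cohort's current mean scores, with separate coefficient sets
for primary and secondary. The orientation is
`P(mainstream) = plogis(cut1 − η)`, `η = β_vabs·VABS + β_iq·IQ`: with the
negative fitted coefficients this sends higher-functioning cohorts to
mainstream settings; the opposite orientation puts essentially the whole
cohort in special provision at any plausible score and cannot be the
intended reading. The mix is frozen within each phase (re-evaluating as
scores drift is available but placement is modelled as a decision taken at
phase entry).

**Utility.** A published regression for autistic children maps state to
utility: constant −0.2438, age 0.0119/year, age² 0.0003, ADOS −0.0063,
log IQ 0.0304, VABS 0.0103. Its description names *baseline* cognitive
ability and symptom severity as predictors, so by default IQ and ADOS are
held at baseline inside the utility equation while VABS and age vary
(`utility_time_varying_iq` switches this). QALYs accumulate as monthly
utility × survival / 12, discounted mid-cycle.

**Costs.** Intervention costs accrue for the 24 treatment months (ABA) and
the TAU costing window (default, also 24 months). Schooling costs are the
placement-weighted mean of the three annual unit costs (£4,418 / £8,690 /
£15,703) over the school months. Social care and medical costs follow an
annual regression on both scores (intercept £1,900.09, −£8.78 per VABS
point, −£7.81 per IQ point), floored at zero, over the whole childhood
horizon — an extrapolation of a regression estimated in adolescents, which
the base case inherits deliberately.

## Scenario analyses

**Observed placement** (`scenario = "placement"`): the regression link from
scores to schooling is replaced with placement proportions observed in
follow-up studies (ABA 30/38/32%, TAU 1/27/72%), applied for all school
years. This isolates how much of the result rides on the indirect
score→placement link.

**Lifetime adult phase** (`scenario = "adult"`): the horizon extends to age
80. At 18.5 the cohort's VABS is mapped to five adult independence levels
("completely independent" … "completely dependent") by an ordered logit;
levels are then constant for life. Because published evidence reports only
*per-level summary statistics*, the model reproduces the published
procedure: it simulates individual records from configurable per-level VABS
means and prevalences (`simulate_adult_ipd()`) and fits the ordered logit
to them (`fit_independence_model()`, maximum likelihood via `MASS::polr`,
with a ridge-penalised fallback when levels are perfectly separated).
Externally known coefficients can be injected through
`settings$adult$coefficients` instead. Each level carries an annual cost
bundle assembled from published adult unit costs (residential care, day
services, respite, and so on), constrained to be non-increasing with
independence. Adult utility holds age at 18 with a configurable per-decade
decrement (default zero, as the published decrement schedule is not
reproducible from available sources); scores are frozen at their 18.5
values. The per-level means, prevalences, and bundle compositions are
explicitly *synthetic defaults*, not published values: the true values live
in an unavailable technical report, so they are configuration, chosen once
to span the plausible VABS range (85/70/57.5/45/30, SD 8) with roughly even
prevalences.

Two structural facts follow from the model and are used as checks: under
pessimistic durability the arms' scores have converged by 18.5, so the
adult phase cancels exactly and the lifetime ICER equals the childhood
ICER; under optimistic durability the treated arm's higher VABS shifts the
independence mix enough that ABA dominates (saves money and gains QALYs)
over a lifetime.

## Sensitivity analysis

`run_dsa()` varies each non-fixed parameter to its lower and upper bound
(95% limits) with everything else at means — two full model runs per
parameter — and ranks parameters by the absolute ICER range (tornado).
`run_psa()` draws every non-fixed parameter independently: normals for
regression coefficients and score changes, moment-matched gammas for costs,
moment-matched betas for proportions, and truncated normals for bounded
continuous quantities reported with a "beta-binomial"-style distribution (a
beta-binomial is undefined for a continuous score; the truncated normal
respects the printed bounds). Draws that break the model — a non-positive
IQ anywhere on a trajectory, or placement cut-points out of order — are
redrawn with a counter. No correlation structure is imposed: the source
reports none, and coefficient-wise sampling of regression blocks without
their covariance is a known limitation that widens placement uncertainty.

The PSA summary ICER is the ratio of mean incrementals, never the mean of
per-iteration ICERs (the ratio-of-means convention is the only one robust
to sign changes). `ceac()` converts iterations to a cost-effectiveness
acceptability curve; the default criterion is positive incremental net
monetary benefit (`λ·ΔQALY − Δcost > 0`), with the literal ratio rule
(`Δcost/ΔQALY < λ`, which misclassifies dominated iterations) available
for comparison with spreadsheet implementations.

## Numerical choices

* Flows are evaluated at cycle-start states and discounted at cycle
  midpoints (`(1+r)^(−(t+0.5)/12)`); annual step discounting is available
  (`discounting = "annual"`) and changes totals by well under 1%.
* The social/medical regression is floored at zero; utilities are *not*
  capped at 1 by default. The cap (`utility_cap_at_one`) never binds in the
  deterministic base case, but under parameter sampling it truncates the
  treated arm's utility draws and biases incremental QALYs towards zero by
  10–15%, an artefact rather than a feature — the published probabilistic
  means show no such shrink, so the default is off.
* The ordered-logit fit is deterministic given the simulated records and
  seed; separation triggers a flagged ridge-penalised fit (`λ = 10⁻³` on
  the slope) rather than a silent divergence.
* Observed placement mixes are renormalised to sum to one; placement
  probabilities sum to one exactly by construction (differences of
  cumulative logistics).

## Reconciling the printed inputs

Several rows of the published input table are internally inconsistent, and
the defaults reconcile them deterministically (each is visible in
`param_table(aba_parameters())`):

* the *secondary-school* placement block's lower/upper columns are
  cyclically shifted by two rows (each coefficient's mean ± 1.96 SE
  reproduces the bounds printed two rows away); they are re-attached;
* the utility block's ADOS and VABS bounds are swapped relative to their
  means and SEs; re-swapped;
* the primary cut-1 SE is printed as 0.02 yet its bounds span 4.66; the SE
  is recomputed as span/3.92 = 1.19;
* the intellectual-disability proportion's bounds duplicate the IQ row's;
  recomputed from its SE.

## Calibration of under-specified details

Three implementation details of the original spreadsheet analysis are not
recoverable from its description: the TAU costing window (treatment lasts
24 months but the pre-school phase only 18), monthly versus annual discount
stepping, and whether IQ is time-varying inside the utility equation.
`calibrate_variants()` runs all eight combinations and tabulates the six
deterministic ICERs against the published values so the choice is
documented rather than silent. The best-matching combination — TAU window
24 months, IQ frozen at baseline, monthly discounting, mean absolute error
about 6% across the six ICERs — coincides with the most literal reading of
the published description, and is the default.

Two aspects of the published results are *not* reproducible from the
printed inputs, and the package does not pretend otherwise:

* **Absolute QALY levels.** The printed utility coefficients give a
  baseline utility of 0.526 (which matches the published example
  arithmetic) rising with age, hence TAU QALYs of about 7.3 over the
  discounted 15.5-year horizon. The published TAU total of 4.37 would need
  a mean utility near 0.36, which no reading of the printed coefficients
  produces. *Incremental* QALYs — differences between arms, in which the
  level terms cancel — reproduce well (0.22–0.24 pessimistic and 0.79–0.86
  optimistic depending on the utility-IQ switch, against published
  unrounded values 0.2444 and 0.8372).
* **The pessimistic schooling offset.** The published incremental costs
  imply an education cost offset of about £13.9k under pessimistic
  durability, roughly double what the printed placement coefficients yield
  (£7.6k): by month 102 the pessimistic effect has fully washed out, so
  secondary placement cannot differ between arms. Simultaneously the
  published *optimistic* offset (£21.0k) exceeds what same-mix-throughout
  placement would give, so no single placement rule matches both rows.
  The public-sector pessimistic ICER therefore lands about 15% high, and
  this propagates to the corresponding probabilistic summary (whose shift
  *relative to the deterministic value*, +5.4%, matches the published
  +5.2%).

## What the synthetic data do and do not show

The synthetic life table is Gompertz–Makeham with defaults giving
childhood cumulative mortality below 0.5% over the childhood horizon —
deliberately negligible, as with real national rates — and plausible
old-age mortality for the lifetime scenario; it does not reproduce any
particular national schedule. The simulated adult records exercise the
ordered-logit fitting machinery with known structure (parameter recovery at
n = 5,000 is tested to within 10% on the slope), but their per-level means
and prevalences are configuration, not evidence: passing tests show the
pipeline is faithful to its specification, not that the adult-phase
defaults predict real adult outcomes.

## Problem sizes

The deterministic model evaluates 186 monthly cycles (924 in the lifetime
scenario) in a few milliseconds. The probabilistic analysis uses 10,000
iterations, as in the original analysis, and runs in well under a minute;
the test suite exercises the full 10,000 twice and smaller runs elsewhere.
The one-way sensitivity analysis covers the 42 parameters that carry
distributions (84 model runs).

## Known limitations

* Parameters are sampled independently; regression blocks lack their joint
  covariance.
* The adult phase's level means, prevalences and cost-bundle compositions
  are synthetic configuration defaults.
* The mortality relative risk (default 2.56) is a placeholder consistent
  with registry-based estimates, not an input printed with this analysis;
  childhood results are insensitive to it.
* Carer/parent quality of life, treatment discontinuation, and
  out-of-pocket or productivity costs are out of scope, as in the original
  analysis.
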