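---
title: "Modelling maternal mortality with maternalsim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maternal mortality with maternalsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternalsim)
```

## The model

`maternalsim` is an individual-based, monthly-cycle microsimulation of
women's reproductive life courses, built to estimate maternal mortality
indicators in settings where deaths are incompletely reported. Each
simulated woman carries her own demographic attributes (country, urban or
rural residence, education), fertility preferences, contraceptive state,
pregnancy state and clinical history. The population is open: new women
enter at age 10 each January according to an entry schedule, and women
leave through death or on reaching age 60. Calendar time advances in
monthly cycles, and every cycle applies a fixed canonical event order to
each living woman:

1. person-time accrual and background (non-obstetric) mortality,
2. aging and menopause checks,
3. the family-planning update (intentions, method adoption, switching,
   discontinuation),
4. a conception attempt,
5. the pregnancy-month update (ectopic resolution, induced-abortion
   decision, miscarriage, antepartum stillbirth, delivery with its care
   pathway),
6. the postpartum update (breastfeeding clock, late maternal hazard),
7. appending new entrants.

The event order within a cycle is not something monthly-resolution data
can identify, but it does affect results (for example, whether a woman can
die of background causes in the same cycle she would have delivered), so
it is frozen and documented here rather than left to chance.

### Demography

All-cause female mortality comes from annual lifetables by single age and
year, converted to monthly probabilities by
`m = 1 - (1 - q)^(1/12)` so that twelve compounded monthly draws
reproduce the annual risk. Maternal-death definitions exclude accidental
and incidental deaths, so each non-obstetric death is first classified as
injury-related with an age-stable probability; non-injury deaths that
occur during pregnancy or the 42-day postpartum window become indirect
maternal deaths with a calibratable probability, reflecting conditions
aggravated by pregnancy. All deaths in the window, of any cause, count as
pregnancy-related. Monthly resolution cannot represent 42 days exactly;
the window is approximated as the pregnancy plus one full postpartum
cycle, and the late-maternal window as postpartum cycles 2-12. This
over-counts the window by up to 18 days per death; at monthly resolution
this is the smallest consistent approximation and it is applied
identically to the maternal and pregnancy-related numerators, so ratios
between them are unaffected.

Compositional change that the mechanistic model does not carry (migration,
differential background mortality) is handled the way survey statisticians
poststratify: `raking_weights()` runs iterative proportional fitting of a
subgroup-by-age-band table to target margins, and the resulting weights
multiply every tally contribution.

### Reproduction and family planning

Fecundity is an age-banded monthly probability (piecewise-constant over
5-year bands; a stand-in for spline age schedules, adequate at monthly
resolution). Conception requires sexual debut (log-normal age, subgroup
specific) and is suppressed by contraception (method-specific annual
failure probabilities converted to monthly) or damped by lactational
amenorrhea for up to nine months postpartum. Desired family size is an
inflated Poisson; a woman with that many living children is limiting,
one who gave birth within the spacing window (24 months) is spacing, and
otherwise she desires a birth soon. Intentions drive the contraception
state machine: met need is a year-trended probability evaluated when need
first arises (debut, postpartum, intention change) and re-evaluated each
January so secular trends in access can act; methods come from
intention-specific mixes; spacing episodes have exponential durations
followed by a switch-versus-discontinue draw; permanent methods are
absorbing.

Pregnancies carry twins with a monozygotic-plus-dizygotic(age)
probability, fetal sex from the primary sex ratio, and a delivery month
drawn once from a categorical fetal lifetable over gestational months
7-10. Losses are applied in fixed order each month: ectopic pregnancies
(elevated after a previous ectopic) resolve at month 3 through the same
recognition/referral/treatment pathway as delivery complications;
unintended pregnancies face a single induced-abortion decision at month 1
(inside the decision window of months 1-4; one decision per pregnancy
matches a per-pregnancy incidence); miscarriage hazards apply in months
1-5 (doubled by history); antepartum stillbirth hazards apply per fetus
from month 6 (with a male excess). Sex-selective abortion is modelled by
multiplying the abortion probability of all-female pregnancies by the
factor that maps the primary to the secondary sex ratio in expectation:
`f = (1 - (SR1/SR2)(1 - a)) / a`, which equals 1 when the two ratios
agree.

### The care pathway

Deliveries start at one of five sites ordered by emergency obstetric care
capability (Home, Home with skilled attendant, non-EmOC facility, BEmOC,
CEmOC), drawn from a year- and subgroup-trended multinomial. Five direct
complication groups (pre-eclampsia/eclampsia, obstructed labor, postpartum
hemorrhage, sepsis, other direct) occur with base rates scaled by
individual risk factors (age bands, anemia, multiple gestation, history of
pre-eclampsia, C-section for sepsis). The three-delays cascade then runs
per complication: recognition (higher for severe cases, at better sites,
and boosted by antenatal-care visits and partograph monitoring), timely
transport, and a referral target allowing horizontal transfer and
facility bypass, capped at two hops and never moving downward.

Interventions follow an availability/efficacy/effectiveness contract:
`RR_applied = 1 - a * kappa * (1 - RR_efficacy)`, with `a` the
site-year availability and `kappa` a site quality factor in [0, 1]. This
linear interpolation between no effect and full efficacy is the simplest
composition satisfying the contract's endpoints (no availability or no
quality means no effect; full availability at full quality delivers the
trial efficacy). Preventive interventions (active management of the third
stage of labor, clean delivery) multiply complication incidence;
partograph monitoring adds to obstructed-labor recognition on the logit
scale; curative interventions multiply the case fatality rate at the
treatment site. Severity-specific case fatality rates fall with site
capability; severe complications never treated at an adequate site impose
an intrapartum-stillbirth risk per fetus. A woman with several
simultaneously fatal draws dies once, attributed by a fixed cause priority
(hemorrhage, sepsis, hypertensive, obstructed, other direct, abortive) —
an arbitrary but deterministic rule required by at-most-one-death
bookkeeping. Late maternal deaths apply a monthly hazard in postpartum
cycles 2-12.

Because the model is fitted to *reported* deaths, underreporting is
explicit: each maternal death is captured by CRVS with a site- and
year-trended probability, and by survey-style active case finding with a
probability constrained to be at least as high (a non-negative logit
boost). Reported counts can therefore never exceed true counts, per
source and cell.

### Indicators

Six indicators are computed from event tallies: the maternal mortality
ratio (maternal deaths within the 42-day window per 100,000 live births),
the pregnancy mortality ratio (all deaths in the window per 100,000 live
births), the proportional mortality ratio (maternal deaths as a
percentage of all deaths among women 15-49), the maternal mortality rate
(per 100,000 woman-years 15-49), total maternal deaths (maternal plus
late), and the lifetime risk of maternal death (the sum of age-specific
maternal mortality rates over ages 15-49). Uncertainty intervals are the
2.5 and 97.5 empirical percentiles across simulation iterations using the
linear-interpolation convention (`quantile` type 7), frozen so intervals
are reproducible. Maternal deaths at ages outside 15-49 (possible when a
conception shortly before 50 ends after the 50th birthday) are included
in ratio numerators but excluded from rate denominators and lifetime
risk, mirroring the indicator definitions.

## The synthetic world

Real applications of such a model consume national lifetables, survey
microdata and vital registration. The package instead ships a generator,
`generate_synthetic_world()`, that produces a small self-consistent world
with the same *structure* — UN-style female lifetables with a secular
decline, an entry schedule, DHS-style subgroup composition (urban/rural by
three education levels), family-planning, health-system and complication
parameters — and records the exact truth used. Country values are drawn
through a five-level hierarchical prior catalogue (global, income group,
continent, region, country): one normal offset per hierarchy node, summed
along each country's ancestor path on the transformed scale (logit for
probabilities, log for rates, identity otherwise), so countries sharing
upper levels are correlated, exactly as hierarchical shrinkage assumes.

Generator defaults aim at a plausible high-burden setting: peak monthly
fecundity 0.20, twin probability around 1-2%, primary sex ratio 1.05,
miscarriage hazard ~2%/month (months 1-5), ectopic incidence 1.5% per
conception with a 3-fold recurrence, antepartum stillbirth hazard
~0.4%/month, desired family size with mean around 3.2 and an inflation
point at 2, met need near 45% rising ~0.04 logits/year, complication
incidence per delivery between 2% (other direct) and 6% (hemorrhage),
severe case fatality at home between 5% (other) and 22% (hemorrhage)
falling roughly tenfold at CEmOC, and CRVS capture around 55% at baseline
with facility deaths more likely to be registered. These yield simulated
maternal mortality ratios from several hundred up to above one thousand
per 100,000 — the range observed in the highest-burden countries —
declining over time through site and intervention trends.

What the generator deliberately does *not* emulate: real age-pattern
detail (fertility splines, heaping), HIV/malaria epidemiology behind
indirect deaths, facility congestion, COVID-era disruptions, and
inter-country migration flows (raking re-weights composition only).
Passing tests on this world therefore demonstrate that the machinery is
correct and the inference calibrated under the model's own assumptions,
not that the defaults describe any particular country.

`generate_synthetic_targets()` closes the loop: it runs the engine under
the recorded truth, applies underreporting, averages a small number of
replicates, adds truncated Gaussian observation noise (sd 1 death) and
tags a train/test split by year — reported-death targets of exactly the
kind vital-registration systems produce, with a known generating process.

## Calibration and posterior predictive checks

All free parameters are fitted simultaneously by simulated annealing.
The goodness of fit is a sum of squared scaled distances; the per-target
scale defaults to `max(|obs|, 10)` so country-years with large counts do
not dominate (setting the scale to 1 recovers the plain sum of squared
distances). Proposals perturb a random subset of parameters on the
transformed scale with standard deviation 0.25 times the prior sd, with a
10% chance of a fresh prior draw to escape local basins; acceptance is
Metropolis with geometric cooling, and the starting temperature is set
from probe evaluations so early uphill moves are accepted with probability
about 0.8. Every evaluation is archived; the best 100 unique parameter
sets act as the calibration posterior, resampled uniformly with fresh
first-order seeds so that downstream intervals carry both parameter and
stochastic uncertainty. Evaluations share a common random-number seed so
goodness-of-fit comparisons between parameter sets are not drowned in
first-order noise.

The posterior predictive check compares 95% prediction intervals from the
resampled posterior with the observed targets: the coverage probability
(share of targets inside their interval), the mean absolute error and the
mean error, reported per cause group and per train/test split.

The packaged end-to-end experiment uses three countries, 250 agents per
country, years 1989-2010 with reporting from 1994, targets for total and
cause-specific reported deaths per country-year, a 2006 train/test cut,
2000 annealing evaluations and 120 posterior predictive iterations. These
sizes were chosen once, from engine throughput, as the package's standard
desk-scale experiment; the mechanics are identical at larger scale. At
desk scale the reported-death counts are small, so the calibration
posterior remains prior-dominated for weakly identified parameters — the
check of interest is that the truth lies inside the central 80% archive
range for most parameters and that predictive coverage is near nominal,
not that point estimates pin the truth.

## Numerical choices and edge cases

* Probability-scale parameters are clipped into [0, 1] after risk
  multipliers; a clip triggers a one-time warning per run.
* Zero denominators (no births, no person-time at an age) raise explicit
  undefined-indicator errors rather than returning NaN; the long-form
  indicator writer drops an indicator (with a warning) when a tiny world
  cannot support it.
* Iterative proportional fitting requires the two margin totals to agree
  within 0.5 and errors on infeasible targets (positive target over an
  empty margin) or non-convergence, reporting the residual.
* Menopause ages are truncated to 40-60 years; hemoglobin gains from
  antenatal care are capped at 16 g/dL without ever lowering a higher
  draw; anemia uses the WHO 11/12 g/dL cuts.
* Women exit the modelled window at age 60; exits are not deaths and do
  not enter any tally.
* All randomness flows from one seeded stream with a fixed vectorised
  processing order, so every mode is bit-reproducible given its seeds;
  per-woman counter-based streams would add invariance to processing
  order, which a fixed order already guarantees.

### What calibration can and cannot do at desk scale

A property of the sum-of-squared-distances score deserves emphasis.
Predictions enter the score as single stochastic engine runs, so for a
target cell with expected count `lambda` the score contribution under the
generating truth is about `1.5 * lambda` (Poisson variance of the
prediction plus that of the target), whereas predicting zero contributes
about `lambda^2` plus smaller terms. Below roughly `lambda = 0.6` the
degenerate zero prediction therefore *out-scores the truth*, and the
best-fitting archive drifts toward under-reporting/under-prediction
parameter regions. Cause-resolved country-year death counts in a
desk-scale world sit well below that threshold, so the packaged
experiment demonstrates the full calibration machinery — annealing,
archiving, resampling, predictive checks — while its parameter-recovery
performance is structurally limited by count sparsity, not by the
optimiser. With data volumes where counts per cell are well above one
(as in national vital-registration data), the same inequality reverses
and the score prefers the truth. Users calibrating to sparse counts
should aggregate targets (over years or causes) until expected cells
exceed a few events, or replace the quadratic score with a count
likelihood.

## Known limitations

Monthly resolution blurs sub-month timing (the 42-day window, early
neonatal events). The five method classes and single met-need probability
compress contraceptive dynamics. Indirect deaths are a single proportion,
not disease-specific. The trend damping form — effective time
`(1 - alpha^t)/(1 - alpha)`, the partial geometric sum — is one natural
family of weakly monotone, bounded trends (linear at `alpha = 1`, bounded
for `alpha < 1`); other saturating forms would fit the same contract.
Desk-scale worlds produce sparse death counts, so cause-specific
calibration is noisy by construction; the package's calibration checks
are about interval calibration, not point recovery.
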