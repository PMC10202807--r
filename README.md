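# maternalsim

Maternal mortality is still measured badly where it is highest: deaths
have many causes, and vital-registration systems miss a large share of
them. `maternalsim` approaches the measurement problem structurally: it
simulates the reproductive life course of individual women month by
month — fertility preferences, contraception, pregnancy and its losses, a
five-tier emergency obstetric care cascade, cause-specific mortality and
*underreporting* — and then fits all model parameters simultaneously to
reported death counts, so that quantities observed with more certainty
(births, reported deaths by cause) inform parameters that are uncertain
or unobserved (case fatality, reporting completeness).

The package is a desk-scale, fully testable implementation of that
programme, built around a synthetic world with known ground truth:

* **Engine** — an open-population monthly microsimulation
  (`simulate_world()`, `advance_month()`): background mortality with
  injury exclusion and indirect-death classification, sexual debut,
  inflated-Poisson family-size preferences, a contraception state machine
  (met need, method mix, exponential durations, switching), conception
  with lactational amenorrhea, twins and sex ratios, miscarriage, ectopic
  pregnancy, induced (possibly unsafe, possibly sex-selective) abortion,
  antepartum stillbirth, five delivery sites, obstetric complications
  with individual risk factors, the recognition → transport → referral
  ("three delays") cascade, intervention availability/efficacy/
  effectiveness, late maternal deaths, and CRVS-vs-survey underreporting.
* **Hierarchical priors and trends** — country parameters resolved
  through a five-level hierarchy (global, income group, continent,
  region, country) on logit/log/identity scales (`parameter_prior()`,
  `resolve_parameter()`), with damped time trends
  `b + c * (1 - alpha^t)/(1 - alpha)` (`trend_spec()`, `trend_value()`).
* **Indicators** — maternal mortality ratio (MMR), pregnancy mortality
  ratio, proportional mortality ratio, maternal mortality rate, total
  maternal deaths, lifetime risk; means with 95% uncertainty intervals
  across iterations (`mmr()`, `indicator_suite()`, `lifetime_risk()`,
  `uncertainty()`).
* **Calibration** — simulated annealing against reported-death targets
  with a sum-of-squared scaled distances score (`anneal()`,
  `goodness_of_fit()`), a best-100 posterior archive resampled with fresh
  first-order seeds (`posterior_sample()`), and posterior predictive
  checks reporting coverage probability, MAE and ME per train/test split
  (`ppc()`, `ppc_world()`).
* **Synthetic world** — `generate_synthetic_world()` /
  `generate_synthetic_targets()` stand in for the real demographic and
  survey inputs and record the exact truth, so calibration can be tested
  against a known answer.
* **Poststratification** — raking / iterative proportional fitting
  (`raking_weights()`) for compositional re-weighting.

## A worked example

```r
library(maternalsim)

gen <- generate_synthetic_world(3, seed = 424, years = 1989:2010,
                                report_from = 1994, n_agents = 250)
tallies <- lapply(1:6, function(i) {
  restrict_tally(simulate_world(gen$world, gen$truth, seed = i), 1994:2010)
})
ind <- indicator_table(tallies, scope = "global")
subset(ind, year == 2010 &
         indicator %in% c("mmr", "lifetime_risk", "total_maternal_deaths"))
#>   scope scope_id year             indicator     mean    ui_lo    ui_hi
#>  global   GLOBAL 2010                   mmr 1.34e+03 98.42520 2.27e+03
#>  global   GLOBAL 2010         lifetime_risk 5.82e-02  0.00524 9.24e-02
#>  global   GLOBAL 2010 total_maternal_deaths 1.67e+00  0.12500 3.75e+00
```

This seed draws a very-high-burden world: an MMR around 1,300 per
100,000 live births and a lifetime risk near 6% sit at the top of the
range observed in the hardest-hit countries. With only ~750 simulated
women the absolute annual death count is small (mean 1.7 here) and the
uncertainty intervals are correspondingly wide — which is why indicators
are always reported with intervals across iterations and why calibration
targets pool causes and years.

Calibrating to the world's own reported-death targets and checking the
posterior predictively:

```r
tg    <- generate_synthetic_targets(gen$world, gen$truth, reps = 2,
                                    noise_sd = 1, seed = 424,
                                    cut_year = 2006)
train <- tg[tg$split == "train", ]
free  <- free_parameters(gen$world)
arch  <- anneal(make_prior_sampler(free),
                make_simulator(gen$world, gen$truth, train), train,
                anneal_config(steps = 2000,
                              proposal_scale = free$prior_sd * 0.25,
                              seed = 4242))
pw    <- ppc_world(gen$world, gen$truth, arch, tg, k = 100, n = 120,
                   seed = 77)
subset(pw$report, group == "all")
```

The report lists, per split, the share of observed targets inside the
95% prediction interval (coverage), the mean absolute error and the mean
error of the predictive means.

## Package layout

```
R/                    engine, priors/trends, synthetic world, indicators,
                      calibration, raking, IO
tests/testthat/       unit + property tests per module, plus the
                      end-to-end acceptance suite
scripts/acceptance.R  headline-quantity reproduction script
vignettes/            methods vignette (model, assumptions, design)
inst/cli/             command-line wrapper
```
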