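---
title: "Modelling a national type 2 diabetes epidemic: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a national type 2 diabetes epidemic: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model implemented by `t2dmdyn`, the choices made
where the design was genuinely open, and what the test suite does and does
not demonstrate about real data.

## The model

`t2dmdyn` implements a deterministic, age- and sex-structured compartmental
model of type 2 diabetes mellitus (T2DM) at the population level. The
population is stratified by:

* **sex** (male, female),
* **age band** — 20 five-year bands spanning ages 0–100 by default,
* **risk profile** — the 8 combinations of three binary risk factors:
  obesity, smoking, and physical inactivity (the all-negative profile is
  "healthy"),
* **T2DM status** (non-diabetic, diabetic).

This gives 2 × 20 × 8 × 2 = **640 coupled ordinary differential
equations**, integrated in continuous calendar time from 1950 to 2050.
States at year *Y* are snapshots at *Y*.0; flows credited to year *Y* are
integrated over [*Y*, *Y*+1).

The flows are:

* **births** at a crude birth rate (piecewise-linear in time over knots
  every 10 years, fitted) into the youngest band, split by a sex ratio at
  birth of 1.05 (configurable), all newborns healthy and non-diabetic;
* **aging** between adjacent bands at 1/(band width) per year; aging out of
  the last band is treated as mortality;
* **background mortality** per sex and band (a fixed schedule — a declining
  early-childhood component plus a Gompertz adult component — scaled by a
  fitted per-sex multiplier), multiplied by a relative risk of mortality in
  the diabetic compartments (proportional hazards);
* **risk-factor onset and reversal** per factor, sex and band, identical
  inside diabetic and non-diabetic compartments. The obesity onset hazard is
  additionally multiplied by a per-sex calendar trend: 1 up to 1990, linear
  to a fitted value at 2050, constant after. Smoking and inactivity rates
  are constant in time, so their prevalence changes only through the
  demographic structure;
* **T2DM incidence** from each non-diabetic compartment into the
  same-profile diabetic compartment, at the baseline (healthy-profile)
  hazard for the sex/band multiplied by the relative risk of every factor
  present in the profile. T2DM is absorbing: there is no remission flow.

**Multiplicative risk combination.** Published estimates rarely report
joint relative risks for factor combinations, so the hazard for a profile
multiplies the single-factor relative risks. This is the standard
assumption in this model family; the combination rule is isolated in one
place (`t2dm_hazard()`) should an alternative be needed.

**Adult-only epidemiology.** T2DM incidence and risk-factor transitions are
active only in bands with midpoint ≥ 20 years. The surveys being emulated
cover adults, and all reported outcomes use the 20–79 age range, so
childhood rates are unidentifiable; setting them to zero is the neutral
choice.

**No migration.** The demography has births, deaths and aging only.
Sudden population inflows (refugee waves) are deliberately not modelled;
the demographic calibration therefore smooths over them.

## Rate parameterization

Fitting one free rate per band would mean hundreds of parameters.
Instead, each rate family is a continuous age curve: log-rates at a few age
knots, interpolated log-linearly onto band midpoints (flat beyond the
outer knots).

* baseline T2DM incidence: knots at ages 20/35/50/65/80, per sex (10
  parameters);
* each of the six risk-factor onset/reversal families: knots at ages
  20/40/60, per sex (36 parameters);
* initial (1950) prevalences of T2DM and each factor, per sex, on the logit
  scale, shared across adult bands at initialization (8 parameters);
* the per-sex obesity trend multiplier at 2050 (2 parameters).

All bounds are wide but finite (rates span roughly 1e-5–0.6 per
person-year on the log scale); the knot sets are configurable.

## Calibration

Calibration is weighted least squares: the squared differences between
modelled and observed prevalences, weighted by each record's sex-specific
survey response rate (normalized to mean 1), plus relative squared errors
for demographic targets. The minimizer is a **bounded Nelder–Mead
simplex**: an unconstrained simplex (standard 1, 2, 1/2, 1/2 coefficients)
run on coordinates mapped into their boxes by the periodic transform
`x = lo + (hi − lo)(sin u + 1)/2`, so the objective is never evaluated
outside bounds and boundary optima are reachable. Termination is an
absolute tolerance (default 1e-4) on the spread of cost values across the
simplex; a failed simulation maps to a large finite penalty (1e12) so the
simplex can retreat.

**Two stages.** The demographic series (thousands of residuals) and the
survey prevalences (hundreds) have no natural common scale. Rather than
pick an arbitrary trade-off weight, the default fit is staged: stage 1
frees the demographic parameters against the population series; stage 2
frees the epidemiological parameters with demography fixed. A `joint` mode
with an explicit scale weight exists for sensitivity checks.

**Block-cyclic sweeps.** A single ~56-parameter simplex reliably stalls.
The model's structure makes the epidemiological parameters nearly
separable: risk-factor dynamics do not depend on the T2DM stock, and the
two sexes are fully decoupled given demography. Stage 2 therefore sweeps
eight low-dimensional blocks (each factor and the T2DM incidence family,
one sex at a time) cyclically, each with its own bounded simplex; two
cycles by default, three for the highest-accuracy recovery experiments.
Warm restarts between cycles act as simplex restarts, which is the
standard remedy for Nelder–Mead stagnation.

**Regularization.** An optional ridge penalty on bound-normalized
parameters (`lambda * sum(((theta - theta_ref)/(hi - lo))^2)`, reference =
mid-bounds by default) guards against parameters drifting to extremes when
data are sparse. It is off by default.

**Numerical tolerances.** Projection runs integrate at rtol 1e-8 / atol
1e-6 persons. Inside the cost function the tolerances are relaxed to
1e-6 / 1e-3: the cost surface needs far less resolution than reported
outputs, and the looser tolerance makes thousands of evaluations cheap.
Fits are deterministic; reproducibility comes from the recorded start
point (mid-bounds by default), not from seeds.

## Epidemiological outputs

Reported quantities use ages 20–79 ([20, 80) in the half-open band
convention): prevalence, people living with T2DM, annual new cases (the
incidence flow integrated over the year), and the incidence rate per 1,000
person-years **at risk** — person-years of the non-diabetic population,
trapezoidal between consecutive year snapshots. The at-risk denominator is
one of two defensible readings of "incidence rate"; it is the one
consistent with the hazard-based model structure, and it is isolated in
`epi_report()`.

**Attributable fractions.** For each stratum (sex × band × profile) the
instantaneous excess incidence over the healthy-profile hazard is
`N λ0 (RR − 1)`. Within a stratum carrying several factors, the excess is
apportioned to each factor proportionally to `(rr − 1)`; this scheme is
additive, order-free, conserves the stratum excess exactly, and reduces to
Levin's formula when one factor acts alone. An alternative
average-sequential-removal scheme (Shapley-style over removal orderings,
which also conserves the excess) is available via `method = "sequential"`.
A counterfactual oracle — recompute the year's incidence flow with a
factor's RR set to 1, occupancies held fixed — verifies the decomposition:
the two agree exactly in every one-factor configuration, and the sum of
apportioned fractions equals the all-factors-removed counterfactual by
construction.

## Health expenditure

The attribution assumes people with T2DM spend `r` times as much per
capita on health care as people without (`r` ∈ {2, 3} brackets published
estimates). Solving `pc · N = e (N_nonDM + r N_DM)` for the non-diabetic
per-person spend `e` gives per-case attributable spend `(r − 1) e` and an
attributable share `(r − 1) f / (1 + (r − 1) f)` of national expenditure,
where `f` is the **all-age** diabetic fraction — the reading consistent
with converting economy-wide per-capita expenditure. Historical per-capita
expenditure is either held at its last historical value after 2015 or
extrapolated on an OLS linear trend (floored at zero); report years before
the series' first historical year (the source series starts in 1995, while
reports run from 1990) are back-filled on the same trend. No discounting,
no currency adjustment.

## Uncertainty

Two Monte Carlo refit analyses, 1,000 runs each by default:

* **parameter uncertainty**: the four relative risks are sampled from
  lognormal distributions median-anchored at the point estimate with
  `sdlog = (log hi − log lo)/(2 × 1.96)` from their 95% CIs;
* **data uncertainty**: every survey prevalence is multiplied
  independently by U(0.6, 1.4) and clipped to [0, 1].

Each run refits the epidemiological stage only (demography fixed,
warm-started at the base calibration — the sampled quantities do not
affect demography, and this keeps 1,000 refits tractable), then records
the projected prevalence; the 95% uncertainty interval is the empirical
2.5–97.5% envelope across completed runs. Run *i* draws with seed
`seed + i`, so runs are order-independent and the analysis is exactly
reproducible. Failed runs are logged and excluded; more than 10% failures
raises a flag.

## The synthetic-data generator

No survey microdata are shipped; the generator replaces them. It emulates
six cross-sectional surveys (1994–2017) with the published sex-specific
sample sizes and response rates — including the strong response-rate
asymmetry between men and women — reporting each outcome in 10-year age
groups from the design's adult lower age to 80 plus a whole-range summary
row (266 prevalence measures in total). Observed prevalences are binomial
draws with the sex sample allocated over age groups in proportion to the
model population; an opt-in sex-differential bias multiplier exercises the
response-weighting rationale. Demographic targets are yearly totals
(1950–2020) plus decennial age/sex counts read off the truth trajectory,
optionally with lognormal noise; the expenditure series rises to exactly
$257 per capita in 2015.

The generator's default parameters are fixed (not seed-dependent) and were
chosen once so the emergent prevalences sit where the emulated national
surveys sit: adult T2DM around 14% in 1990 rising past 20% by 2050, men
above women; obesity 25–50% with women well above men and rising; smoking
strongly sex-differentiated (men ≈ 40%, women ≈ 10%) and flat; inactivity
10–25%.

What the generator does **not** reproduce: real survey design effects
(clustering, stratification), non-binomial measurement error, diagnostic
differences between surveys, secular changes in definitions, and migration
shocks. Passing the recovery tests therefore shows that the estimation
machinery can invert the model's own data-generating process at realistic
noise levels — not that the model is correct for any particular country.

## Problem sizes in the test suite

The test suite runs the noise-free recovery experiment at full resolution
(640 equations, 266 measures, three block cycles at tolerance 1e-7), the
noisy recovery at two cycles / 1e-6, and the Monte Carlo machinery at 50
runs with a reduced refit budget (T2DM block only, one cycle) — a
scaled-down version of the 1,000-run production setting. Dynamics-level
property tests use a 10-band configuration where full resolution adds
nothing.

One recovery limit is worth stating plainly: with the emulated sample
sizes, binomial noise in the smallest old-age cells reaches several
percentage points and is occasionally coherent across surveys; no
estimator can recover truth at such a cell more accurately than the noise
it was shown. Cell-level recovery under noise is therefore bounded by the
realized noise (mean error ≈ 1 pp, worst cells several pp), while
noise-free recovery is tight (≤ 0.25 pp at every cell).

## Known limitations

* Parameter identifiability is not formally analysed; the model is used to
  capture trends, and distinct rate combinations can produce near-identical
  prevalence surfaces. The regularized and Monte Carlo refits are the
  practical guard.
* The obesity trend is a single linear multiplier per sex on onset
  hazards — a parsimonious stand-in for unknown time-varying rates.
* Aging out of the open-ended last band is treated as mortality, slightly
  overstating death rates at ages 95+.
* The economics module attributes expenditure, it does not model costs:
  indirect costs, discounting and currency effects are out of scope.
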