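---
title: "Estimating field active metabolic rates of fishes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating field active metabolic rates of fishes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fishes dominate consumer biomass on many reefs, but their metabolic demand
in the wild is hard to measure: respirometry gives the standard metabolic
rate (SMR, the rate of an inactive, fasting fish) and the maximum metabolic
rate (MMR, the aerobic rate at exhaustive exercise), while free-living fish
operate somewhere in between. `fishamr` estimates the activity component of
field metabolic rate - the rate at the *average field swimming speed*,
AMRfield - by combining three data streams:

1. laboratory intermittent-closed respirometry (SMR, MMR vs body mass),
2. field swimming speeds from calibrated stereo-video tracking, and
3. maximum swimming speeds from flume trials, compiled across families.

## The interpolation model

Aerobic metabolic rate in fishes rises approximately exponentially with
swimming speed, i.e. linearly on the log scale. Anchoring that line at SMR
(speed zero) and MMR (maximum speed `vmax`) gives, for a fish swimming at
its average field speed `vfield`,

    log10 AMRfield = log10 SMR + (log10 MMR - log10 SMR) * vfield / vmax

Two identities follow and are enforced to numerical precision: at
`vfield = 0` the rate is SMR; at `vfield = vmax` it is MMR; at half the
maximum speed it is the geometric mean `sqrt(SMR * MMR)`. AMRfield is *not*
capped at MMR: when the relative speed `vfield/vmax` grows with body size,
the mass-scaling exponent of AMRfield can exceed that of MMR, and the
implementation must be able to represent that. Extrapolations beyond
`vmax` are counted and reported, never silently truncated.

Two derived scopes summarize activity:

* **FAS** (factorial aerobic scope) `= MMR / SMR`;
* **FSA** (factorial scope for activity)
  `= ((24 - t) * AMRfield + t * SMR) / (24 * SMR)`, the day-averaged
  multiple of SMR for a fish resting `t` hours per day at SMR. The default
  `t = 12` assumes diurnal activity and nocturnal rest; `t` is a
  per-species trait so nocturnally active species can be explored by
  changing one number.

## Component regressions

All three component quantities come from hierarchical Bayesian regressions
(sampled with JAGS through `rjags`):

* **Metabolic rates.** `log10 MR ~ Normal(mu, sigma)` with
  `mu = (a + a_jk) + (b + b_jk) * log10 mass`, where `j` indexes species
  and `k` the rate type (SMR or MMR), so each species-by-type cell gets
  its own intercept and slope around the global allometry, and the two
  rate types of one species are fitted jointly. The global slope (the
  metabolic scaling exponent) carries an informative `Normal(0.75, 0.1)`
  prior, the canonical allometric value; everything else is weakly
  informative.
* **Field speed.** `log10 v ~ Student-t(nu, mu, sigma)` with species-level
  intercepts and slopes on `log10 length`. The heavy-tailed likelihood is
  deliberate: stereo-video speeds include bursts and tracking errors, and
  the t likelihood downweights them where a Normal fit would be dragged.
* **Maximum speed.** As the speed model, but groups are
  family-by-body-shape combinations and caudal aspect ratio enters
  linearly with one global coefficient, so species never measured in a
  flume can be predicted from their family, shape and aspect ratio - for
  unseen groups the prediction marginalizes over the group distribution,
  widening the interval rather than failing.

Per-species coefficients are always reported as the *sum* of global and
group draws, computed draw-wise so their posterior covariance is kept.

### Priors and sampler settings

Defaults (all overridable in `fit_settings()`): intercepts
`Normal(0, 5)`; group-offset SDs and the residual SD half-`Normal(0, 1)`;
degrees of freedom `Gamma(2, 0.1)` truncated to `nu > 2` (finite
variance); aspect-ratio coefficient `Normal(0, 5)`; 4 chains, 1000
adaptation and 1000 burn-in iterations, 2500 retained draws per chain.
Convergence is a contract, not a hope: every monitored parameter must have
split R-hat at or below 1.01 and effective sample size at least 400, or the
fit raises a condition that still carries the draws for inspection.

### Numerical choices

* **Hierarchical centering.** Group coefficients are sampled *centred on
  the globals* (`a_sp[j] ~ N(a, sd)`), with offsets derived afterwards.
  The equivalent global-plus-offset parameterisation mixes an order of
  magnitude worse here because the global intercept and the offset mean
  trade off freely.
* **Covariate centering.** Sampling uses `log10 mass` (or length) centred
  at its mean, and aspect ratio split into group means (absorbed into the
  group-intercept prior) plus within-group deviations - an exact
  reparameterisation; draws are mapped back to the natural
  parameterisation before any diagnostic or summary is computed, so users
  only ever see natural-scale parameters.
* **Canonical row order.** Inputs are sorted internally before sampling,
  so posteriors are exactly invariant to input row permutations at a fixed
  seed.
* **Determinism.** Every chain receives an RNG seed derived from the
  user's seed; identical data and seed give bit-identical draws.

## Respirometry extraction

Cycle oxygen-decline slopes (mg O2 L^-1 min^-1) convert to whole-animal
rates with the effective water volume, `chamber - mass/1000` litres
(tissue density 1 g ml^-1). MMR is the first closed cycle, measured
immediately after the exhaustive chase. SMR is the mean of the lowest 10%
of cycle rates (pool size `ceiling(0.1 n)`, so small trials keep at least
one value) after two steps whose details published protocols usually leave
open and which are therefore explicit, configurable choices here:

* the first cycle is excluded from the SMR pool (it is the MMR
  measurement by construction);
* outliers are rates outside `median +/- 3 * scaled MAD` of the pool - a
  deterministic, robust rule. It is designed for the tight plateau that
  dominates a long trial; it will not (and should not) flag points in
  data with no plateau structure.

Trials whose extracted SMR exceeds their MMR are excluded with a logged
reason rather than silently clamped.

## Stereo-video corrections

Video length measurements drift linearly with distance from the nearest
camera, so a per-system calibration regression of (measured - true) length
on camera distance is fitted and subtracted from all lengths and
displacement distances; each track segment uses its mean camera distance.
Speeds are straight-line (chord) displacements over 3-5 s windows -
segments outside the window are dropped with a log message - and an
individual's final length and speed are plain means of its three length
replicates and its 3-5 segment speeds. A corrected length or distance that
comes out negative is an input error, never a silent zero.

## Propagating uncertainty to the size grid

For each species and each integer centimetre of its length range, mass
comes from the length-weight power law `W = a L^b`; SMR, MMR and vmax
enter as posterior *medians* of their expected values, while `n_iter`
(default 1000) posterior draws of the expected field speed are pushed
through the interpolation to give draws of AMRfield and FSA; FAS is
computed draw-wise from the joint SMR/MMR posterior. This asymmetry -
medians for the laboratory quantities inside AMRfield, full draws for the
field speed and for FAS - is kept deliberately: the field-speed posterior
is by far the widest component, and FAS should reflect the covariation of
the two laboratory rates. Predictions use the posterior of the *expected*
response (no residual noise): `vfield` is an average speed, and the other
components enter as medians; posterior-predictive draws are available
behind `include_residual = TRUE`. Summaries are means, SDs and
equal-tailed 95% credible intervals.

## Assemblage scale-up

Visual-census records (site, transect, area, species, length to the
nearest cm, count) are matched to the species-by-nearest-cm grid cell
(half-up rounding); per-transect totals `sum(count * rate)` are divided by
transect area, and sites are summarized as the mean and SD across transect
*densities* - not pooled counts - because transect areas can differ. The
site-level AMRfield/SMR ratio is taken from the site means. Totals are
exactly additive over record partitions and linear in counts, which the
test suite asserts as conservation properties.

## What the synthetic generators emulate - and what they do not

The generators produce all five input tables from known ground truth: the
default study emulates a six-species reef survey with ~11 respirometry
trials per species (150 cycles each, ~24 h of 8-min cycles), ~105 filmed
individuals per species, ~32 flume records per species, and a 13-site
census with three 50 m^2 transects of ~21 fish each. Key default scales:
log10 residual SD 0.05 for metabolic rates, 0.37 for field speeds (the
dispersion typical of stereo-video speed data), 0.05 for maximum speeds;
Student-t degrees of freedom 5 and 10; masses log-uniform on 5-500 g
(log-uniform sampling spreads leverage evenly across the allometry, which
stabilises slope estimation).

Structural choices worth knowing:

* SMR and MMR residuals of one individual are correlated (`rho`, default
  0.5), mirroring the within-individual covariation of the two rates. No
  published estimate of this correlation exists to our knowledge, so it is
  a free knob of the generator, not an inferred quantity.
* Respirometry trials place the true MMR in cycle 1, decay back to the
  SMR plateau over 30 cycles, and add only non-negative activity bumps -
  so the lower envelope *is* the SMR, and with all noise at zero the
  extractors recover truth exactly (the round-trip tests rely on this).
  Gross outliers are injected as multiplicative factors far below 0.5
  into post-recovery cycles, the regime the MAD rule is designed for.
* Census abundances are multinomial over configured shares; lengths are
  uniform over each species' range.

What passing tests on these data do **not** show: the generators draw
masses and lengths independently per table (no shared individuals), have
no temperature structure, no diel activity cycle, no background (microbial)
respiration, and no digestion or reproduction costs - AMRfield is the
activity component of field metabolism only. Parameter recovery on
synthetic data demonstrates the estimation machinery is correct under the
assumed data-generating process, not that the process captures every
feature of real reef data.

## Problem sizes and run times

The bundled analysis (`analysis/01_simulate.R` ... `05_assemblage.R`) uses
the study sizes above; the three fits take a few minutes in total, the
rest is seconds. The test suite uses smaller fixtures (2-6 species, tens
of observations, 2 short chains where only point recovery matters) chosen
so the whole suite runs in about a minute while still exercising every
contract; simulation-based checks (coverage, robustness) use 10-20
replicates with tolerances set from the corresponding binomial or
sampling-error bounds.

## Known limitations

* `vmax` for species never tested in a flume rests on the
  family-by-shape-by-aspect-ratio model; within-group variation in
  swimming ability is real and unmodelled.
* The log-linear speed-metabolism relation is an assumption; species with
  a plateau near top speed will have AMRfield overestimated at high
  relative speeds.
* The chase protocol behind first-cycle MMR can underestimate the true
  maximum for species that reach higher rates while swimming.
* FSA assumes rest at exactly SMR for exactly `t` hours; flexible or
  nocturnal activity biases FSA downward unless `t` is adjusted.
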