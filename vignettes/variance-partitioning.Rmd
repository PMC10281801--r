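---
title: "Proximity-based social phenotypes and their variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-based social phenotypes and their variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sociality)
```

## The problem

Longitudinal behavioural studies of individually identified animals (here
modelled on repeated transect surveys of a habituated lizard population)
yield georeferenced sighting records: one row per individual per half-day
survey, with sex, date, coordinates and a behaviour code. From these the
package constructs yearly, sex-partitioned social phenotypes and asks three
questions with Bayesian multivariate mixed models:

1. Are social behaviours *repeatable* — do individuals differ consistently
   across years?
2. Do the behaviours *covary at the among-individual level* (a behavioural
   syndrome)?
3. Do repeatable social behaviours *covary with fitness* (number of
   offspring surviving to adulthood)?

Each question is asked per sex, and each behaviour is computed separately
toward opposite-sex (OS) and same-sex (SS) conspecifics.

## Social phenotypes

A *survey* is one half-day session; multiple fixes of an individual within a
survey collapse to one presence carrying the first fix. An *association* is
a pair of individuals within 1.85 m of each other in the same survey, with a
closed boundary (a pair at exactly 1.85 m associates; the tie-break is
deterministic and the radius configurable). No transitive closure is
applied.

All social behaviour is evaluated inside each individual's *core home range*
(HR50): an association event is credited to a focal only when the focal's
own fix lies inside its own HR50. Because the restriction is focal-sided,
the two members of a dyad can disagree in their event counts; each focal's
metrics use its own event set.

Per individual-year and sex class:

- **Social tendency** — proportion of the focal's in-core sightings with at
  least one association event.
- **Degree** — number of distinct associates.
- **Mean HWI** — the half-weight association index, averaged over the
  focal's associates. For a dyad seen together-and-associated in `x`
  surveys, apart in `yA`/`yB`, and together-but-not-associated in `yAB`:

  HWI = x / (x + yAB + 0.5 (yA + yB))

  This is the Cairns–Schwager form, the standard correction for sampling
  periods in which only one member was observed. "Seen" in the denominators
  means detected in the survey; `x` additionally requires the focal-sided
  in-core event. A focal with degree zero gets mean HWI 0 by convention.
- **Conspecific density** — distinct OS (or SS) individuals with at least
  one sighting inside the focal's HR50 that year, divided by the HR50 area.
  The count is of individuals, not sightings, so duplicated fixes change
  nothing. Units are individuals per square metre; for core ranges of a few
  hundred square metres this puts densities on the order of 0.001–0.1.
- **Social dominance** — the proportion of the focal's yearly sightings
  whose behaviour code is aggressive (used as a fixed effect in fitness
  models).

Two eligibility thresholds are deliberately distinct knobs: at least 25
sightings for home-range and density estimation, at least 30 for inclusion
in social analyses. Every filter step logs rows in and rows out.

## Core home ranges

The utilization distribution is a product-Gaussian kernel density estimate
on a square grid (default 1 m cells) padded at least `3h` beyond the data,
normalized to unit mass; the smoothing parameter defaults to `h = 7` m, a
value previously optimized for this study system and treated as fixed (no
cross-validation is attempted). The HR50 is extracted greedily: cells are
accumulated in decreasing density order until half the probability mass is
reached, so the region's mass lies within one cell's mass above 0.50 and
the area error is bounded by one cell per contour step. Point-in-range
tests use the containing cell with no sub-cell interpolation, which keeps
the pipeline bit-reproducible. For a circular bivariate normal cloud the
HR50 area approaches the analytic `2 pi sigma^2 ln 2`, which the test suite
checks at sigma = 20 m within 10%.

## The multivariate mixed model

Yearly measures of trait *k* for individual *i* in year *t* are modelled on
a latent scale:

eta_ikt = x'_ikt beta_k + a_ik + y_kt (+ e_ikt)

with per-trait intercepts and fixed effects (sighting count and years since
maturity, centred and scaled), individual effects `a`, year effects `y`, and
residuals. Gaussian traits (tendency, mean HWI, density — centred and
scaled to unit variance first) take the latent value directly; count traits
(degree, offspring) are Poisson with log link and an observation-level
Gaussian residual (log-normal overdispersion), without which the latent
residual variance would be undefined.

Random structures follow two conventions:

- **idh** — heterogeneous per-trait variances, zero covariances (used for
  repeatability models; year effects are always idh).
- **corgh** — variances fixed to 1, free correlations (used to estimate
  among-individual correlations directly).

Sampling is delegated to JAGS through rjags; any correct sampler satisfies
the same contract, and the test suite checks the posterior against one-way
ANOVA and sample-correlation oracles on simulated data. Free variances get
scaled-inverse-chi-square priors — `tau ~ Gamma(nu/2, nu/2)` on the
precision, i.e. scale 1 with a small degree of belief — with `nu = 0.002`
for random effects and `nu = 0.02` for residuals; fixed effects get diffuse
normal priors. An optional parameter-expanded (multiplicative redundant)
parametrization is available for the idh variances as a prior-robustness
check; the suite verifies it leaves posterior mean variance components
unchanged to within 0.05 on standardized traits.

The corgh correlation matrix is parametrized by its unit-row Cholesky
factor: each subdiagonal slot carries a coefficient in (-1, 1), scaled so
each row has unit norm. Any draw is a valid correlation matrix, marginal
variances are exactly 1 by construction, and for two traits the implied
prior on the correlation is exactly uniform on (-1, 1); for more traits it
remains symmetric around zero and weakly informative. This replaces the
inverse-Wishart-style prior of the source framework: a Wishart node cannot
be sampled once its scale is normalized out, whereas every parameter here
is a scalar with full conditional support.

Initialization: Poisson latents start at `log(y + 0.5)` (centred),
intercepts at response means, free residual precisions at inverse sample
variances, correlations at zero; the RNG seed is mandatory and fixes the
entire chain.

### Convergence gates

Chains are gated on effective sample size (floor 1000 at study-scale run
lengths) and lag-1 autocorrelation of the thinned chain (ceiling 0.1).
Failing models are flagged `converged = FALSE` in the output tables and the
run continues; constant chains (fixed variances) are excluded from gating
because their autocorrelation is undefined. Desk-scale defaults
(`iterations = 10000`, thinning 5) are deliberately far below the study
conventions (millions of iterations, thinning 1000), which remain available
through the configuration; at desk scale the gates will typically flag the
slower-mixing parameters, which is informative rather than fatal.

## Repeatability

Latent-scale repeatability is computed draw-wise as

R = V_I / (V_I + V_R)

The denominator deliberately excludes the year variance: this is adjusted
(year-conditional) repeatability, matching the estimand used for the yearly
social measures. For Poisson log-link traits the components are transformed
to the observed scale draw-wise via the log-normal–Poisson moments: with
`lambda = exp(mu + (V_I + V_R)/2)`,

- `V_I_obs = lambda^2 (exp(V_I) - 1)`
- `V_P_obs = lambda^2 (exp(V_I + V_R) - 1) + lambda`
- `R_obs = V_I_obs / V_P_obs`

The additive `lambda` is Poisson sampling variance, so `R_obs < R_latent`
always; the suite verifies the closed form against a brute-force
Monte-Carlo variance decomposition (10^7 simulated observations) to within
0.005 across a grid of (mu, V_I, V_R). The transformation uses the
intercept-only latent mean — covariates are centred, so the intercept is
the population latent mean; averaging over fixed-effect predictions is a
documented alternative left to the caller (both modes reachable by passing
a different `mu`). Gaussian traits have identity link, so latent and
observed scales coincide exactly.

Intervals are 95% highest-posterior-density by default (quantile intervals
by flag); an effect is "significant" when its interval excludes zero. Sex
contrasts pair draws from the two sexes' independent chains, compute the
probability of direction pd of the difference, and report `p = 2 (1 - pd)`.

## Fitness models

Fitness (offspring count) is a single measure per individual, so its
within-individual variance is unidentifiable; following the fixed-to-1
convention, both its residual and individual-level variances are fixed at 1
and only correlations and fixed effects are estimated for that block. The
model is a five-trait corgh: four repeated social traits plus fitness, with
year effects on the repeated traits only. Fixed effects: sightings and age
on the social traits; heterozygosity and yearly-mean social dominance on
fitness (the single-measure row has no natural yearly covariate values, so
fitness receives only its individual-level covariates — a documented
reading of an ambiguous convention, configurable through `trait_spec`).
Individuals maturing at or after a configurable cutoff season are excluded,
since their offspring could not have been genotyped as adults.

**Known limitation.** Fixing among-individual variances to 1 is only
correct when the traits' true among-individual variances (after phenotypic
standardization) are near 1. Simulation shows that when the true
among-individual share is well below 1, realized effect variances shrink
below their fixed values and correlation estimates are rescaled upward —
the linked trait is still detected, and null traits can drift from zero.
This distortion is inherent to the fixed-variance convention (the source
framework behaves the same way), not to the sampler; validation therefore
simulates the unit-variance convention that the fitness link itself is
defined under. Zero-inflated Poisson fitness models are out of scope (they
are documented as non-convergent in this setting).

## The synthetic-data generator

Two levels:

- **Trait panels** draw directly from the model above: joint individual
  effects with a specified among-individual correlation matrix, independent
  year and residual effects, Gaussian or Poisson(log) observation. One
  measure per individual-year by default (matching yearly social measures);
  an unbalanced mode keeps each individual in a random subset of years.
  The fitness generator draws a unit-variance latent effect with specified
  correlation(s) to the (standardized) trait effects — jointly feasible
  weights are solved through the correlation matrix — and one Poisson count
  per individual.
- **Sightings** emulate the survey design: fixed per-survey detection
  probability (default 0.8 — chosen so that realistic survey counts
  straddle the 25- and 30-sighting thresholds and the filter logic is
  genuinely exercised), bivariate-normal movement around fixed home-range
  centres (default jittered grid with 3-SD spacing so chance co-proximity
  is rare), and a social placement pass: a detected individual is relocated
  to within the association radius of a concurrently detected neighbour
  with probability `plogis` of the dyad's mean latent gregariousness.

The sighting simulator targets qualitative structure (metric ranges, sex
partition, nonzero repeatability), not the field study's exact metric
distributions; no distributional facts about detection are available from
the study, so those defaults are fixtures, not estimates. Passing tests on
simulated data therefore demonstrate correctness of the estimators under
the stated model, not goodness of that model for any particular field
population. Fixed seeds make every generator byte-reproducible.

## Problem sizes used in validation

The test suite fits desk-scale models: 200 individuals by 4 years for
recovery checks (repeatability within ±0.07 of truth; corgh correlation
within ±0.10), 20 replicates for interval calibration (at least 85%
coverage), 10 replicates for the fitness-link detection property, and
shortened chains (thousands of iterations) throughout. These sizes are the
package's own validation choices; study-scale chain lengths are available
via configuration and change nothing but Monte-Carlo precision.

## Other design choices and limitations

- The exact supplement conventions for dyadic denominators are not
  recoverable from the study's main text; the conventions above (detection
  -based denominators, focal-sided in-core events) are documented choices.
- Mean HWI is bounded in [0, 1] and the pipeline enforces it.
- Network permutation nulls, centrality metrics, pedigree/genetic effects,
  model comparison and GIS ingestion of real park geometry are out of
  scope.
- Density's numerator (distinct individuals) and units (per m^2) are
  documented choices; the study prints unitless values of the same order.
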