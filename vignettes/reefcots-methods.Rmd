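---
title: "Models and methods behind reefcots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reefcots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

reefcots implements a Bayesian pipeline linking fish biomass removal by
fisheries to Crown-of-Thorns Starfish (CoTS) densities on coral reefs.
This vignette is the package's own account of the models, the synthetic
data that stand in for restricted monitoring and logbook extracts, the
numerical choices, and the limits of what the tests demonstrate.

## The data and their preparation

Three observation tables drive everything.

* **Manta tows**: an observer towed around a reef perimeter records, per
  2-minute tow, a CoTS count and a categorical coral-cover code. The 16
  codes (`0`, `1L`, `1`, `1U`, ..., `5U`) are converted to proportions by
  the mid-point of the interval each represents
  (`convert_cover_category()`); the mapping is injective and
  order-preserving, and both properties are tested. CoTS density is
  standardised to individuals per minute (counts halved, then averaged
  across tows).
* **Retained catch**: kilograms kept per fishery (commercial line, net,
  trawl; recreational charter), 6-by-6-nautical-mile logbook grid site,
  fish group and reporting year (1 July–30 June, labelled by the end
  year; all joins use this label). `aggregate_catch()` sums the four
  fisheries, treats absent fisheries as zero, and logs duplicated fishery
  rows before summing them.
* **Belt transects**: paired fished/unfished reefs, three sites of five
  50 m × 5 m transects each, with counts and individual total lengths.
  Counts scale by 4 to densities per 1000 m²; biomass uses the allometric
  `a·TL^b` with coefficients supplied by the user (the shipped table is a
  synthetic test fixture, not literature values); site mean length pools
  fish across transects (a flat per-fish mean, not a mean of transect
  means — a test pins the distinction on a table where the two differ).

When a grid-site-year holds reefs of both zoning classes,
`resolve_duplicates()` removes the closed-zone reefs (the catch reported
for that cell can only have come from open reefs), then averages
same-zoning reefs with an unweighted mean; tow-count weighting is a
defensible alternative but weights are not knowable from the published
record, and the choice is logged. For the fisheries-lag dataset,
site-years observed in closed zones only are dropped entirely. Every
drop and average lands in a machine-readable audit trail
(`audit_log()`, JSON-lines on disk). `build_lagged_pairs()` then joins
catch in year *t* to CoTS density and same-year coral cover in year
*t + x*, for lags 1–6; its row set equals a brute-force double-loop join
in the tests, and duplicate site-years upstream are a hard error rather
than a silent many-to-many join.

## The three model shapes

All inference is MCMC over one of three shapes built by `build_model()`
(a fourth, gaussian, exists to validate the sampler against conjugate
results).

**Hurdle-gamma** (fisheries-lag cells; reserve biomass and density). An
exact zero occurs with logit-linear probability; positive values are
gamma, parameterised by shape α and mean μ with rate α/μ, so the log
link acts on the mean and a covariate slope is directly a scaling
exponent of the mean. A site-year counts as zero only when its density
is exactly 0 — no epsilon threshold, because the per-minute
standardisation produces exact zeros, never tiny positives. The two
parts share no parameters, so the joint posterior factorises; both parts
are still fitted in one run.

**Negative binomial (NB2)** (zoning model): variance μ + μ²/φ, log link,
closed zoning as the reference level so the intercept β₀ is the unfished
baseline at zero cover, β₁ the open-zoning log fold, β₂ the coral-cover
slope, and a reef-year intercept ζ ~ N(0, σ_ζ). Derived quantities —
exp(β₁), its percent difference, and the range factor exp(2σ_ζ) — are
computed draw by draw and summarised afterwards; for strictly monotone
transforms the quantile summaries commute with the transform up to
interpolation between order statistics, and a constructed two-draw
counterexample in the tests fixes the draw-wise convention.

**Gamma** (site mean length): the positive part alone.

The hurdle-gamma and NB2 log-densities are written out explicitly
(`hurdle_gamma_logdensity()`, `negbin_logpmf()`) because they are the
package's core; they are held to independent oracles — quadrature of the
continuous part, a gamma–Poisson mixture integral, brute-force summation
of the probability mass — at 1e-6 or tighter, and cross-checked against
the base R distributions where they overlap.

## Priors, parameterisation, initial values

Priors default to weakly-informative choices, all overridable through
`default_priors()`: Normal(0, 2.5) slopes, Student-t(3, 0, 2.5)
intercepts, half-Normal(0, 2) hierarchical SDs, half-Normal(0, 5) on the
gamma shape and NB dispersion. One deliberate exception: site-level mean
lengths have a coefficient of variation around 0.04, putting the gamma
shape in the hundreds, so the length model uses a half-Normal(0, 1000)
shape prior — the default scale would truncate the likelihood and bias
the zoning contrast.

Sampling is delegated to JAGS (via rjags), the standard Gibbs/slice
engine for this model class; `build_model()` also exposes the identical
joint log-posterior as a plain R callable, which is what the hand-summed
oracle, gradient and decomposition tests exercise, and `prior_only = TRUE`
drops the likelihood so prior-recovery tests can sample the prior
through the same machinery.

Two numerical choices matter in practice:

* **Centred vs non-centred hierarchical intercepts.** Non-centred
  (u = σ·z) is the default and mixes well when group-level data are weak,
  as in the zoning and lag models. For the reserve models the data pin
  the site/reef intercepts tightly and non-centred sampling stalls (the
  inverted funnel), so those models use the centred form (`re_centred`).
* **Moment-based initial values.** Chains start at the log mean response,
  a method-of-moments shape/dispersion, and the empirical logit of the
  zero fraction. Starting all coefficients at zero can strand a chain in
  a degenerate mode where hierarchical intercepts absorb the intercept;
  the initialisation removes that failure mode. `fit_model()` refuses to
  start if the log-posterior is not finite at the initial point, and
  names the offending values.

In the fisheries-lag model the covariates (log catch + 1, coral cover)
are centred before fitting: with an uncentred covariate mean near 7, the
intercept prior leaks into the correlated slope and shrinks it by a few
hundredths — harmless for the intercept, not for the quantity the whole
grid exists to estimate. Centring shifts only intercepts (an invariance
the tests assert), so the scaling exponent is unchanged. Zero aggregated
catch is handled as log(kg + 1) throughout, generator and model alike.

Convergence is gated, not assumed: split-R̂ (each chain halved) above
1.01 or an effective sample size below 400 for any monitored parameter
flags the fit with a prominent warning and `converged = FALSE`; grid
drivers record per-cell failures instead of dropping cells. Defaults are
4 chains × 1000 warmup × 1000 sampling; the drivers accept smaller
settings and the tests use them. Intervals are equal-tailed quantile
intervals (not HPD), matching the way credible intervals are reported in
this literature; evidence classes use strict thresholds (>80%, >95%) on
the percentage of posterior mass above zero, one-sided because the
hypotheses are directional. No multiplicity adjustment is applied across
the 36-cell grid — instead the report annotates the expected number of
false signals under a global null (5% of cells).

## The synthetic world and what it does (not) emulate

`truth_params()` holds the generative twins of everything the analyses
estimate. Defaults are the study conditions: zoning log fold log 2.8,
coral slope −0.45, reef-year SD 3.77, and a tow-count intercept of −8.2
chosen so the marginal mean is ≈0.34 CoTS per tow once the lognormal
reef-year variance is folded in — i.e. almost all reef-years near zero,
outbreak reef-years in the hundreds, matching the zero-heavy, hugely
overdispersed character of manta-tow data. Catch is lognormal
(median 500 kg per site-group-year, log-SD 1.5) with a cross-group
correlation matrix (validated for symmetry, unit diagonal and positive
semi-definiteness, with the failing eigenvalue named) realised exactly —
persistent site offsets share the same correlation so they cannot dilute
it; the default matrix couples coral trout with rockcods at 0.95 and the
two emperor aggregates at 0.92, reproducing the near-collinear catch
series that make the grid's cells mutually confounded, deliberately.
Coral cover is a latent Beta proportion snapped to the nearest category
mid-point — the simplest mechanism consistent with the conversion table.
Reserve-world multipliers on transect counts (1.25–1.5) and lengths
(1.04–1.12) imply biomass folds of about 1.4–2.1 through the
length-weight cube. One global seed spawns per-table sub-seeds, so each
table is independently reproducible and identical seeds give
byte-identical worlds.

Two generative twins exist for CoTS, on purpose. Tow-level surveys
(`simulate_cots_surveys()`) draw negative-binomial counts with zeros
from the count process alone — no structural zero inflation, consistent
with what the zero-fraction posterior predictive check finds on such
data. They are the twin of the zoning model. The fisheries-lag recovery
study instead uses `simulate_lag_siteyears()`, which draws site-year
densities directly from the hurdle-gamma family (baseline logit zero
probability, coral slopes on both parts, gamma shape 1.2, site SD 0.4).
The reason is an estimand subtlety worth stating plainly: when site-year
densities are built from zero-heavy tow counts, a site-year is positive
mainly when its reef-year effect is large, so among positive site-years
the catch covariate and the latent effect trade off and the hurdle's
positive-part slope is *attenuated* relative to the tow-level slope,
even while the same machinery recovers slopes at nominal rates on data
drawn from its own family. That is not a sampler defect but a difference
between estimands, and it applies to the real analysis too: the scaling
exponent is a statement about the positive (non-zero) component of CoTS
density, not about the latent count process. Recovery is therefore
validated family-by-family against each model's own twin, and the
end-to-end tow-level path is exercised where the estimands coincide
(low-zero regimes, and the zoning model throughout).

What the generator does not emulate: spatial structure and larval
dispersal (grid sites are exchangeable labels), outbreak wave dynamics
(reef-year effects are iid rather than autocorrelated), observer error
beyond the categorical cover snap, and catch misreporting. Passing
recovery tests therefore show that the estimators recover the parameters
of this structure at these sizes — not that the real data satisfy it.

## Scale of the validation studies

The recovery studies are desk-scale by design: zoning recovery uses 20
worlds of 5 grid sites × 3 reefs × 6 years × 8 tows (≈720 tows, ≈90
reef-years) with 2 chains × (400 + 400) iterations, pooled coverage of
β₁, β₂, σ_ζ required at ≥90%; lag-slope recovery uses 20 worlds of 10
sites × 12 years with slopes {0.3, 0} and 2 × (800 + 1000) iterations;
reserve recovery uses 20 worlds of 6 reef pairs × 4 survey years
(biomass fold truth 1.5 × 1.12³ ≈ 2.11); null calibration fits 72
independent single-cell null worlds and bounds the >95% false-signal
rate by the nominal 5% plus two binomial standard errors. Within one
world the 36 grid cells share a single density series against correlated
catches, so false signals cluster (an entire lag row lighting up at
once); the independent-cell design estimates the same expected rate
without that clustering noise. At these sizes the zoning model's
credible intervals are wide — the worked example in the README shows
exactly how wide — and that is the honest desk-scale picture, not a
defect.

## Known limitations

* The zero-fraction posterior predictive check has limited power against
  structural zeros when the dispersion is free: a negative binomial can
  absorb a large zero excess by shrinking φ, so the check is a
  calibration diagnostic, not a decisive test of zero inflation.
* Bayesian intervals are not confidence intervals; at desk-scale n with
  shrinkage priors their frequentist coverage hovers slightly below
  nominal, which the recovery thresholds (≥90% for 95% intervals)
  acknowledge.
* The grid's cells are mutually dependent through correlated catch
  series; a >95% classification for one group-lag cell is evidence about
  that association, not about which group causally drives it. The
  package reports all 36 cells and never selects among lags.
* The analysis is associational end to end — lagged predictors and
  reserve contrasts, not causal identification.
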