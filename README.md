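# reefcots

Bayesian analysis pipeline for the hypothesis that removing predatory
coral reef fish drives population outbreaks of the Crown-of-Thorns
Starfish (CoTS, *Acanthaster* spp.), the corallivore responsible for
persistent coral loss across Indo-Pacific reefs. The package is aimed at
reef ecologists and fisheries scientists who want to (re)run this style
of analysis on long-term monitoring and fisheries logbook data — or, since
those data are held under restricted access by monitoring and fisheries
agencies, on synthetic data with the same statistical structure and known
ground truth.

## The three analyses

**1. Fisheries-lag grid.** Does fish biomass removal predict CoTS density
x years later? For each fish group g (wrasses, emperors, redthroat and
spangled emperors, tropical snappers, rockcods, coral trout) and each lag
x = 1…6, site-year CoTS density y (individuals per minute of manta tow,
open-zone reefs only) is modelled with a hurdle-gamma:

    P(y = 0)        = logit⁻¹(a₀ + a₁·cover)
    y | y > 0       ~ Gamma(α, α/μ)
    log μ           = b₀ + b₁·cover + b·log(catch kg + 1) + u_site
    u_site          ~ Normal(0, σ_site)

The slope b is the biomass-removal scaling exponent of CoTS density for
cell (g, x) — the quantity of interest in all 36 models. Evidence is
summarised as the percentage of posterior mass above 0, classified with
strict >80% / >95% thresholds.

**2. Paired-reef reserve comparison.** Do no-take marine reserves carry
more of these fish? Biomass and density per 1000 m² (hurdle-gamma, the
logistic part a function of zoning) and site-level mean total length
(gamma), each with zoning (fished = reference) as fixed effect and
hierarchical intercepts for site, reef pair, reef and year. The
unfished:fished contrast is computed draw by draw — for hurdle responses
as the expected-value ratio (occupancy ratio × conditional-mean ratio) —
and reported as a fold change and as a percent of the fished value.

**3. Zoning model of CoTS density.** Are CoTS denser on fished reefs?
Tow-level CoTS counts follow a negative binomial (NB2):

    y_tow ~ NB(μ, φ),  log μ = β₀ + β₁·[open] + β₂·cover + ζ_reef-year
    ζ ~ Normal(0, σ_ζ)

with closed (unfished) zoning as reference, so exp(β₁) is the open:closed
density fold ratio, β₂ the coral-cover slope, and exp(2σ_ζ) the
multiplicative range of reef-year effects. All models are fitted by MCMC
(JAGS) with split-R̂ / effective-sample-size gates, weakly-informative
priors, and a posterior predictive check of the zero fraction for the
count model.

The synthetic-data module generates all three observation tables —
fisheries retained catch per 6×6-nautical-mile grid site with
cross-group-correlated log-catch, zero-heavy manta-tow surveys with huge
reef-year variance, and paired-reef belt transects with zoning
multipliers on counts and lengths — from explicit `truth_params()`, so
every estimate above can be validated by parameter recovery.

## Worked example

```r
library(reefcots)

cfg   <- world_config(n_grid_sites = 6, reefs_per_site = 3, years = 1998:2003,
                      tows_per_reef_year = 8, seed = 7)
world <- simulate_world(cfg)   # default truths: beta1 = log 2.8, beta2 = -0.45, sigma = 3.77
zon   <- run_cots_zoning_model(world$manta, chains = 2, warmup = 500,
                               iter = 1000, seed = 3)
zon$summary
#> # A tibble: 4 × 8
#>   parameter  median    l60   u60    l95   u95 pct_above_zero class
#>   <chr>       <dbl>  <dbl> <dbl>  <dbl> <dbl>          <dbl> <chr>
#> 1 b0         -7.85  -9.70  -6.64 -12.1  -5.26            0   none
#> 2 b1          0.375 -0.803  1.47  -2.25  3.32           59.8 none
#> 3 b2         -0.238 -1.68   1.38  -3.52  3.51           44.4 none
#> 4 sigma_zeta  3.03   2.60   3.74   2.05  4.55          100   >95%

zon$derived
#> # A tibble: 4 × 4
#>   quantity               median     l95     u95
#>   <chr>                   <dbl>   <dbl>   <dbl>
#> 1 zoning_fold             1.45    0.106   27.7
#> 2 zoning_pct_diff        45.4   -89.4   2675.
#> 3 reefyear_range_factor 432.     60.5   8997.
#> 4 coral_slope            -0.238  -3.52     3.51
```

Every 95% interval covers its generating truth (β₁ = log 2.8 ≈ 1.03,
β₂ = −0.45, σ_ζ = 3.77): at this deliberately tiny scale — 864 tows on 18
reefs versus >150,000 tows on 490 reefs in a real campaign — the reef-year
SD is well identified (and classified >95%, as its posterior is entirely
positive) while the zoning and coral effects are honest but wide. Larger
worlds tighten them; the multi-replicate recovery tests in
`tests/testthat/test-acceptance.R` quantify coverage. The same world
feeds the other two analyses via `prepare_datasets()`,
`run_fisheries_lag_grid()` and `run_reserve_fish_models()`, and
`run_pipeline()` drives all stages from a single YAML config (a thin CLI
wrapper lives in `inst/cli/reefcots.R`).

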