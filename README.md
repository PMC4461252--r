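# albipm — integrated population modelling of shy albatross under bycatch and climate forcing

`albipm` implements an integrated population model (IPM) for the shy
albatross (*Thalassarche cauta*) colony on Albatross Island, Tasmania — a
population recovering from 19th-century feather and egg harvesting while
exposed to trawl and longline bycatch and to climate variability at the
breeding site. The package is aimed at quantitative ecologists and fisheries
scientists who want to partition the influence of fisheries and environment
on a long-lived seabird within a single estimation framework, and to project
the population under future climate and bycatch-mitigation options.

The pipeline has five working parts, each usable on its own:

* **Spatial overlap** — Argos-style speed/spike filtering and linear
  interpolation of satellite tracks, Gaussian kernel utilisation
  distributions on a 1° grid over the foraging range (45°S–30°S,
  123°E–151°E), and effort-weighted overlap indices
  `O(f, y, s) = Σ_cells E(f, y, c) · U_s(c)` per super-fleet (trawl,
  pelagic longline, demersal longline), year and life stage.
* **Environmental covariates** — chick-window (Feb–May) rainfall totals
  with day-of-year gap imputation, counts of days with maximum temperature
  above 23 °C, annually averaged sea-surface height anomaly (SSHA);
  standardization to x ~ (0, 1); climate-model post-processing (fixed
  rainfall bias offset, percentile regression mapping modelled daily
  averages to observed daily maxima).
* **Population model** — a monthly, age-, stage- and sex-structured
  deterministic engine starting in 1942 from a harvest-depleted state
  (`h_pre × K`, with K = 12 000 pairs). Chick mortality is density
  dependent and environmentally forced:
  `M_y0 = -log(s(N_b)) × Π_i exp(θ_i · sgn(x_i) |x_i|^b)`,
  with `s(N) = s_K + (s_max − s_K)(1 − (N/K)^z_c)` anchored so breeding
  success at K equals the pristine value `bs0`. Fishing mortality is
  `F = q_f · O(f, y, s)` through competing exponential risks; the death of
  either parent fails the nest.
* **Estimation** — a composite likelihood over breeding-pair counts
  (lognormal), breeding success, juvenile and adult survival and one
  low-weight trawl bycatch-rate observation (normal), with pox-outbreak
  seasons excluded; BFGS on transformed parameters with multi-start,
  curvature standard errors, likelihood-ratio/AIC covariate selection
  (models `RTS`, `xTS`, …, `xxx`), and sensitivity re-fits.
* **Projection** — continuation to 2100 under climate-model or
  climate-neutral covariate futures, bycatch mitigation fractions 0–1, and
  SSHA upwelling scenarios, with medians-vs-neutral summaries and the
  smallest offsetting mitigation level.

A first-class synthetic-data generator (`truth_config()`,
`simulate_dataset()`) produces every input the pipeline consumes from a
known-parameter world — clustered tracks, smooth effort surfaces, weather
with known covariate structure, and observation noise conjugate to the
likelihood — so the whole chain is testable end-to-end against truth.

## Worked example

```r
library(albipm)

# a complete synthetic study from known truth (M = 0.041, bs0 = 0.42, ...)
sim <- simulate_dataset(truth_config())

# fit the full covariate model and the covariate-free null
yrs <- 1942:2010
fit  <- fit_population(sim$obs, sim$forcings, yrs, subset = "RTS", b = 1,
                       fixed = "z_c", base_params = truth_config()$params)
null <- fit_population(sim$obs, sim$forcings, yrs, subset = "xxx", b = 1,
                       fixed = "z_c", base_params = truth_config()$params)
tidy(fit)
#> # A tibble: 7 × 3
#>   term                 estimate    std_error
#>   <chr>                   <dbl>        <dbl>
#> 1 M                    4.03e- 2 0.00253
#> 2 bs0                  4.39e- 1 0.0264
#> 3 q_trawl              1.07e- 4 0.0000373
#> 4 q_pelagic            1.24e-10 0.0000000226
#> 5 theta_rainfall       2.53e- 1 0.0763
#> 6 theta_threshold_days 2.95e- 1 0.0455
#> 7 theta_ssha           1.59e- 1 0.0516

compare_models(list(fit, null))
#> # A tibble: 2 × 6
#>   model neg_log_lik  stat    df         p   AIC
#>   <chr>       <dbl> <dbl> <int>     <dbl> <dbl>
#> 1 RTS          45.5  59.1     3  9.16e-13  105.
#> 2 xxx          75.0  NA      NA NA         158.
```

The estimates sit within two standard errors of the generating values
(adult natural mortality 0.041, pristine breeding success 0.42, trawl
catchability 9e-5, slopes 0.20 / 0.30 / 0.15), and the three-covariate
model is decisively preferred over the null — the qualitative conclusion
the real monitoring data support: rainfall, hot days and downwelling all
depress breeding success. The pelagic-longline catchability collapses
toward zero here: with no bycatch-rate observation for that fleet and
similar effort histories, the data cannot apportion bycatch between
fleets, only bound their joint toll.

Project the fitted population under a steady warming of the hot-day count
and find the offsetting mitigation level:

```r
warm <- tibble::tibble(year = 2011:2100,
                       rainfall = 180, threshold_days = 12 + 0.1 * (1:90),
                       ssha = -0.03)
proj <- project_population(fit, scenario = warm, mitigation = 0.5, end_year = 2100)
glance(proj)
#>   scenario      mitigation n_draws median_pairs q25_pairs q75_pairs
#> 1 climate_model        0.5       1        2275.     2275.     2275.
mitigation_threshold(fit, scenario = warm)
#> [1] 0.7  (attained)
```

`autoplot()` methods draw the utilisation grids, observed-vs-expected fit
panels, and projection fans.

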