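---
title: "Methods: an integrated population model for shy albatross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated population model for shy albatross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the population
model and its assumptions, the parameters that matter, the estimation
machinery, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was genuinely
open.

## The study system and the modelling problem

The shy albatross colony on Albatross Island (Bass Strait, Tasmania) was
reduced to a few hundred breeding pairs by feather and egg harvesting and
has been recovering for a century. Two stressors act on it today:
incidental bycatch in trawl and longline fisheries that overlap its
unusually restricted foraging range, and local environmental conditions —
rainfall, heat and upwelling strength — during chick rearing. Because the
colony's at-sea range is compact and well tracked, and because a 30-year
monitoring program provides counts, breeding success, survival and
recruitment data, the two influences can be separated inside one
estimation framework instead of being regressed one at a time. That is
what this package implements: an integrated population model whose
likelihood conditions simultaneously on all monitoring series and on a
single fleet-wide bycatch-rate observation.

## Population dynamics

**Calendar.** The model year runs 1 October–30 September; year *y* is the
season starting 1 October of calendar year *y*. Eggs are laid at the
season start; chicks fledge at the end of May (month 8). The chick-rearing
covariate window is February–May by default (configurable).

**Stages and sexes.** Per sex the state holds: chicks (in the nest),
fledged age-0 juveniles (June–September), juvenile age classes 1–4,
pre-breeders by age 5–15 (the maturity ogive reaches 1 at 16), and two
adult pools — birds that attempted breeding this season and adult
non-breeders. Adults need no age classes because all share the adult
mortality rate; the absorbing adult pool is equivalent to an explicit
plus-group. Sexes are modelled separately with identical defaults; pairs
form as the minimum of male and female candidates, so any asymmetry (for
example sex-specific fishing mortality supplied through sex-specific
utilisation grids) propagates to pair formation.

**Monthly competing risks.** Within a month every at-sea group survives
`exp(-(M_g + Σ_f F_{f,g})/12)`, where `M_g` is the group's natural
mortality (adult `M`; first-year juvenile `Mj`; juveniles age 2+ share
`M`) and `F_{f,g} = q_f × O(f, y, stage)` is fishing mortality from the
overlap index. Kills are attributed to fleets by their share of the total
rate. Because rates are constant within a model year, the twelve monthly
multiplications collapse to an exact closed form; `run_population()` uses
the closed form and `monthly = TRUE` re-runs the explicit monthly ledger
(the test suite asserts agreement to 1e-12 and monthly conservation of
individuals).

**Breeding failure from parent death.** Chick feeding requires both
parents, so the chick's monthly survival is multiplied by both parents'
monthly survival probabilities (independence assumed). Failed breeders do
not re-lay within a season.

**Recruitment and breeding frequency.** Pre-breeders first breed according
to the maturity ogive (cumulative probabilities at ages 5–16 from the
mark-recapture program); a bird that attempted last season re-attempts
with the observed annual return rate where available and 0.95 otherwise;
a bird that skipped returns the following season.

## Density dependence and its closure

Extrinsic chick survival falls with breeding density:

    s(N) = s_K + (s_max - s_K) (1 - (N/K)^z_c)

with carrying capacity fixed at K = 12 000 pairs. The anchor `s_K` is tied
to the pristine breeding success `bs0`, so that at `N = K`, mean
environment and no fishing, realised breeding success (extrinsic chick
survival times both-parent season survival) equals `bs0` exactly. `s_max`
(default 0.75) is the compensated ceiling as density falls to zero and
`z_c` shapes the interpolation. Density dependence on juvenile survival is
not enabled by default; the monitoring data in this system support
compensation in chick survival, not juvenile survival.

A subtle point: an arbitrary combination of adult mortality, pristine
breeding success, maturity ogive and return rate does **not** balance at
K. The package closes the life cycle through the first-year juvenile
mortality `Mj`: at replacement, the renewal condition of the annual
life-cycle map is available in closed form, and `Mj` is solved so the
map's dominant eigenvalue is exactly 1 at K. This makes the
carrying-capacity equilibrium a structural property (the test suite holds
it to 1e-13 over a century) rather than a coincidence of inputs. Users may
instead fix `Mj`, in which case K is not guaranteed to be an equilibrium.
One consequence worth knowing: with the printed ogive (mean age at first
breeding ~9.7) and a 0.95 return rate, the closure forces low first-year
survival and caps the unfished population growth rate at roughly 2 % per
year even when chick survival is at its ceiling — the synthetic colony
therefore recovers more slowly than the real one did, and the synthetic
"juvenile survival" observations are on a lower scale than the historical
mark-recapture values.

**Initialization.** The run starts (1942 by default) at the stable
structure of the life-cycle map evaluated at the depleted chick survival,
scaled so the first season's pairs equal `h_pre × K`; `h_pre` summarises
pre-model harvest depletion and may be estimated or fixed.

## Environmental forcing

Chick mortality in year *y* is

    My0 = -log(s(N_b)) × Π_{i ∈ I} exp(θ_i · sgn(x_i) |x_i|^b)

with the product over the included standardized covariates: chick-window
rainfall total (mm), the count of window days whose maximum temperature
strictly exceeds 23 °C, and annual SSHA (m; negative = upwelling). Two
choices deserve comment:

* **Product, not sum.** Combining the per-covariate factors by product
  makes the modifier exactly 1 at mean conditions for any number of
  covariates, which is what "baseline chick mortality at mean
  environment" requires; a sum over factors would inflate mortality by
  the number of covariates at x = 0.
* **Sign-preserving power.** `x^b` is undefined for negative x at
  b = 0.5 and non-monotone at b = 2; `sgn(x)|x|^b` keeps the response
  monotone in each covariate with the sign of θ and continuous at 0 for
  every b. `b` is fixed (0.5, 1 or 2), never estimated; the three values
  give similar in-sample fits but different extrapolation, so analysis
  proceeds by fitting all three.

Covariates are standardized by the mean and sample (n − 1) standard
deviation over the reference series. Future scenario values are
standardized with the **historical** centre and scale, so projected
covariates can exceed the historical range, as intended.

**Climate-model preprocessing.** Modelled chick-window rainfall is shifted
down by a fixed bias offset (default 61.5 mm, the modelled-minus-observed
overlap-period difference) and floored at zero. Modelled daily *average*
temperature is mapped to daily *maxima* by regressing the 5th–95th
observed-maximum percentiles on the modelled-average percentiles over the
overlap period (91 points) and applying the affine map everywhere; the
map is exact whenever the series differ by an affine transform, which the
tests assert.

## Spatial overlap

Tracking fixes are speed- and spike-filtered (great-circle distances via
geosphere; defaults 100 km/h, 15° spike angle with a 2.5 km leg floor),
and filters are iterated to a fixed point so filtering is idempotent.
Gaps strictly between 1 h and 24 h are filled by linear interpolation at
hourly steps. Utilisation distributions are Gaussian kernel densities
(default bandwidth 1°, planar degrees — an adequate approximation over
this 15° latitude span) evaluated at 1° cell centres, divided by the
kernel mass falling inside the region (boundary correction, so uniform
usage yields a uniform surface to the edge), zeroed on cells whose land
fraction exceeds 0.5, and renormalized to sum to one. Cells are indexed
by their lower-left corner with half-open extent. The overlap index is
the effort-weighted utilisation sum per fleet, year and stage — linear in
both inputs, which the tests check against a brute-force cell loop.
Juveniles use the juvenile grid through age 4; pre-breeders and adults the
adult grid; one adult grid serves both sexes unless sex-specific grids are
supplied. Annual effort is spread uniformly over the twelve model months;
monthly effort records are accepted.

## Composite likelihood and estimation

Observation error models: breeding-pair counts (including the single
1972-style count) are lognormal; breeding success, juvenile survival,
adult survival and the bycatch rate are normal. The main text behind this
system states only "likelihood" and "relatively low weight" for the
bycatch datum, so the weights are package choices, config-exposed:
pairs CV 0.10, early count CV 0.30, breeding-success SE 0.05, juvenile
survival SE 0.05 (on the adjusted scale), adult survival SE 0.0045, and
bycatch CV 0.5. Pox-outbreak seasons (1999, 2006 in the real design)
carry exclusion flags and contribute exactly zero. Return rates are used
as dynamics inputs, not likelihood terms.

Juvenile-survival observations are first-year rates; the likelihood
multiplies them by `exp(-3M)` (three additional adult-mortality years) and
compares them with the model's *apparent* survival to age 5, defined as
true survival to 5 times the ogive value at age `T − cohort` (T = final
data year). This reproduces the truncation artifact: recent cohorts have
not finished recruiting, so their apparent survival is biased low in both
the data and the model, and the test suite checks the definition against
a year-by-year recruitment enumeration.

The single adult-survival observation is compared with the mean model
adult survival (including fishing) over the monitoring window. The
bycatch-rate expectation divides the model's kills attributed to the
fleet inside the observation region (default 37–45°S, 135–151°E) by the
fleet's regional effort in thousands.

Free parameters by default: `M`, `bs0`, `z_c`, `q_trawl`, `q_pelagic`,
plus one θ per included covariate; the demersal-longline catchability is
tied to pelagic (the data cannot separate them without a fleet-specific
bycatch observation — the fitted pelagic q often collapses toward zero for
the same reason). Parameters are log-transformed (logit for `bs0`),
optimised by BFGS from a documented default start with ≥5 jittered
multi-starts for real analyses (objective tolerance 1e-9; ties broken by
lowest objective, then smallest parameter norm; the start seed is
recorded in the result). Standard errors come from the inverse curvature
at the optimum, delta-method transformed to the natural scale. AIC is
`2(-lnL) + 2k` with k the number of estimated parameters;
likelihood-ratio tests compare each covariate subset with the
covariate-free model `xxx` on the number of added slopes.

`sensitivity_suite()` re-fits with the early count lowered (2300 → 1500
analogue), and the bycatch observation halved and doubled, warm-starting
from the baseline optimum, reporting parameter deltas and per-fleet kill
totals.

## Projection

`project_population()` continues a fitted trajectory to 2100. Future
effort is the mean overlap of the last five data years per fleet and
stage — the data say nothing about future effort, so it is held constant —
scaled by `1 − mitigation` for the trawl fleet (`all_fleets = TRUE`
extends mitigation to every fleet). Future covariates come either from a
supplied scenario series (a climate model's single trajectory) or from
climate-neutral draws: rainfall and hot-day counts i.i.d. normal with the
historical mean and variance, the counts rounded to non-negative integers
(the discretization is a package choice), SSHA at its historic mean. The
SSHA option replaces the future anomaly with `(1 + m)` times the historic
mean — the linear reading of "m × 100 % stronger upwelling"; how that
phrase maps to the covariate is genuinely open, and this convention is
the simplest monotone one. Summaries use medians across draws with
ratios to the climate-neutral, zero-mitigation median;
`mitigation_threshold()` scans a mitigation grid for the smallest
offsetting level and flags (rather than caps) scenarios that cannot be
offset. Both projection modes — one deterministic trajectory per climate
model, or replicate stochastic draws — are available via `n_draws`.

## The synthetic-data generator

`truth_config()` defines a complete known-parameter study whose defaults
mirror the real design: model years 1942–2010; K = 12 000; adult natural
mortality 0.041; pristine breeding success 0.42; positive covariate
slopes (0.20, 0.30, 0.15); depletion calibrated so the 1972-analogue
count is near 2300 pairs; monitoring gaps copied from the real table
(sporadic early counts, pair counts from 1998, juvenile cohorts
1981–2002, return rates 2000–2010, two pox seasons); three fleets fished
from 1964 with trawl-dominated kills. Tracks are mean-reverting walks
around fixed cluster centres (stationary spread 1.2°, hourly fixes, 10 %
gaps, optional 10×-speed outliers with known labels); effort surfaces are
fixed Gaussian blobs with exactly conserved annual totals and geometric
trends; weather is built so the annual covariates have known structure
(AR(1) rainfall totals around a trend; Poisson hot-day counts realised as
exactly that many above-threshold days, everything else capped below
23 °C); observation noise uses the same error models as the likelihood,
so generator and fitter are conjugate and coverage statements are
meaningful.

What the generator does **not** emulate: behaviourally mechanistic
movement or real oceanography; Argos error classes; immigration between
colonies; pox dynamics (only exclusion flags); and — because of the
life-cycle closure discussed above — the real colony's fast recovery rate
and the scale of its historical juvenile-survival estimates. Passing the
recovery harness therefore demonstrates that the estimation machinery is
consistent and well-calibrated for data generated by this model family,
not that the model is correct for the real colony.

## Problem sizes and numerical choices

The recovery harness fits 20 replicate datasets of 69 model years with
40 observation-years each, sharing tracking and effort data across
replicates (as a real re-analysis would) and regenerating weather and
observation noise per replicate; it fixes `z_c` and `h_pre` at truth —
shape and depletion parameters are weakly informed by a 40-year window
and are conventionally fixed in assessments of this kind — and estimates
`M`, `bs0`, both free catchabilities and all three slopes, using a single
optimisation start per replicate from the documented default start. The
acceptance criterion (coverage of truth within 2 SE for `M` and each θ in
at least 90 % of replicates) runs in a few minutes on one CPU.

Degenerate inputs are handled explicitly: zero-variance covariates are an
error in standardization; zero fixes are an error in the kernel; a life
cycle that cannot replace itself at K (or that renews without
reproduction) is refused at initialization; rates pushed outside [0, 1]
by observation noise are re-truncated with a warning; pair counts above K
are allowed (the density response drops below its anchor) with a one-time
warning. Chick mortality is spread uniformly over the eight chick-rearing
months; effort with annual resolution is spread uniformly over twelve
months.

## Known limitations

The stage bookkeeping, density-dependence form and initialization are the
package's own explicit formulations of a model family whose original full
equations are not public; they are chosen for internal consistency (exact
equilibrium at K, closed-form within-year dynamics) rather than to
reproduce any specific implementation. Fleet-level bycatch attribution is
weakly identified without fleet-specific rate observations. The
environmental response is an exponential in standardized covariates;
extrapolation far outside the historical covariate range is governed by
the fixed power `b` and should be read qualitatively.
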