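#' Ground-truth configuration for the synthetic-data generator
#'
#' Defines the full synthetic study: a known-parameter population, the
#' monitoring design (which observation types exist in which years,
#' mirroring the real monitoring gaps: sporadic early counts, pair counts
#' from 1998, juvenile-survival cohorts 1981-2002, return rates 2000-2010,
#' two pox-outbreak seasons), observation-noise levels matched to the
#' likelihood error models, and stochastic models for weather, SSHA,
#' tracking fixes and fleet effort surfaces. Identical configurations
#' (including `seed`) generate byte-identical data.
#'
#' @param params Truth [albatross_params()]. The default carries adult
#'   natural mortality 0.041, pristine breeding success 0.42, carrying
#'   capacity 12000 pairs, positive covariate slopes, and catchabilities
#'   sized so cumulative bycatch is in the thousands of birds over the
#'   fishing period.
#' @param start_year,n_years Model span (default 1942-2010).
#' @param obs_noise Per-observation-type noise levels (CVs for counts, sds
#'   for rates).
#' @param weather_model Annual-scale weather generator settings: mean/sd/
#'   trend and AR(1) coefficient for chick-window rainfall totals, mean/
#'   trend/sd for hot-day counts, mean/sd for SSHA.
#' @param track_model Tracking generator settings: number of spatial
#'   clusters (or explicit `centres` matrix), cluster spread (degrees),
#'   fixes per bird, birds per stage, gap and outlier fractions, the
#'   plausible speed used to size outliers.
#' @param effort_model Per-fleet annual totals, interannual trend, native
#'   unit, plus the spatial concentration (degrees) of the effort surface
#'   and the fished years.
#' @param design Observation-design windows and pox years.
#' @param seed Integer seed.
#' @return A `truth_config` list.
#' @export
truth_config <- function(
    params = albatross_params(
      M = 0.041, bs0 = 0.42, s_max = 0.75, z_c = 1,
      q = c(trawl = 9e-5, pelagic_longline = 6e-7, demersal_longline = 1.2e-7),
      effect = env_effect(c(rainfall = 0.20, threshold_days = 0.30, ssha = 0.15), b = 1),
      h_pre = 0.12, K = 12000
    ),
    start_year = 1942, n_years = 69,
    obs_noise = list(pairs_cv = 0.10, early_cv = 0.30, bs_sd = 0.05,
                     juv_sd = 0.05, adult_se = 0.0045, bycatch_cv = 0.5,
                     return_sd = 0.03),
    weather_model = list(rain_mean = 180, rain_sd = 40, rain_trend = 0, rain_ar = 0.3,
                         hot_mean = 8, hot_trend = 0.05, hot_sd = 2, hot_ar = 0.3,
                         ssha_mean = -0.03, ssha_sd = 0.04),
    track_model = list(n_clusters = 3,
                       centres = rbind(c(140, -40), c(133, -38), c(146, -41)),
                       spread = 1.2,
                       fixes_per_bird = 150,
                       n_birds = c(juvenile = 11, adult = 55),
                       gap_frac = 0.10, outlier_frac = 0, max_speed = 100),
    effort_model = list(
      fleets = list(
        trawl = list(total = 9000, trend = 0.02, unit = "operations",
                     centre = c(141, -40)),
        pelagic_longline = list(total = 8e5, trend = 0.00, unit = "hooks",
                                centre = c(134, -37)),
        demersal_longline = list(total = 1.5e6, trend = 0.01, unit = "hooks",
                                 centre = c(147, -43))
      ),
      concentration = 4, fishing_years = 1964:2010
    ),
    design = list(early_count_year = 1972, count_years = c(1988, 1989, 1998:2009),
                  bs_years = 1998:2010, juv_years = 1981:2002,
                  return_years = 2000:2010, pox_years = c(1999, 2006),
                  adult_window = 1986:2008, bycatch_year = 2006,
                  bycatch_fleet = "trawl"),
    seed = 42) {
  stopifnot(n_years > 0, all(unlist(obs_noise) >= 0),
            all(track_model$n_birds >= 0), track_model$fixes_per_bird > 0)
  structure(list(params = params, start_year = start_year, n_years = n_years,
                 obs_noise = obs_noise, weather_model = weather_model,
                 track_model = track_model, effort_model = effort_model,
                 design = design, seed = seed),
            class = "truth_config")
}

cfg_years <- function(cfg) seq(cfg$start_year, length.out = cfg$n_years)

#' Generate clustered satellite-tracking fixes
#'
#' Draws fixes from a finite mixture of two-dimensional Gaussian spatial
#' clusters inside the model region. Timestamps are strictly increasing per
#' bird, mostly hourly with a configurable fraction of 1-24 h gaps (to
#' exercise interpolation); a configurable fraction of fixes is displaced
#' far enough to imply ten times the plausible travel speed (to exercise
#' speed filtering with known ground truth).
#'
#' @param cfg A [truth_config()].
#' @param stage `"juvenile"` or `"adult"`.
#' @return Tibble `bird_id`, `t` (POSIXct UTC), `lon`, `lat`, `stage`, and
#'   a logical `outlier` marking the injected implausible fixes.
#' @export
gen_tracks <- function(cfg, stage = c("adult", "juvenile")) {
  stage <- match.arg(stage)
  tm <- cfg$track_model
  n_birds <- tm$n_birds[[stage]]
  if (is.null(n_birds) || n_birds < 1) abort("zero birds requested for this stage")
  set.seed(cfg$seed + 101 + (stage == "juvenile"))
  reg <- ALB_REGION
  centres <- tm$centres
  if (is.null(centres)) {
    centres <- cbind(
      lon = runif(tm$n_clusters, reg[["lon_min"]] + 2, reg[["lon_max"]] - 2),
      lat = runif(tm$n_clusters, reg[["lat_min"]] + 2, reg[["lat_max"]] - 2)
    )
  }
  centres <- matrix(unlist(centres), ncol = 2)
  rows <- map_dfr(seq_len(n_birds), function(b) {
    cl <- centres[sample.int(nrow(centres), 1), ]
    nf <- tm$fixes_per_bird
    gaps <- ifelse(runif(nf - 1) < tm$gap_frac, runif(nf - 1, 1.5, 23.5), 1)
    tt <- as.POSIXct("2004-11-01 00:00:00", tz = "UTC") +
      3600 * 24 * 30 * runif(1) + c(0, cumsum(gaps)) * 3600
    # mean-reverting walk around the cluster centre: stationary sd = spread,
    # hourly steps short enough to stay under the plausible travel speed
    phi <- 0.98
    lon <- lat <- numeric(nf)
    lon[1] <- cl[1] + rnorm(1, 0, tm$spread)
    lat[1] <- cl[2] + rnorm(1, 0, tm$spread)
    if (nf > 1) {
      for (i in 2:nf) {
        ph <- phi^gaps[i - 1]
        sdt <- tm$spread * sqrt(1 - ph^2)
        lon[i] <- cl[1] + ph * (lon[i - 1] - cl[1]) + rnorm(1, 0, sdt)
        lat[i] <- cl[2] + ph * (lat[i - 1] - cl[2]) + rnorm(1, 0, sdt)
      }
    }
    lon <- pmin(pmax(lon, reg[["lon_min"]] + 0.01), reg[["lon_max"]] - 0.01)
    lat <- pmin(pmax(lat, reg[["lat_min"]] + 0.01), reg[["lat_max"]] - 0.01)
    out <- rep(FALSE, nf)
    if (tm$outlier_frac > 0 && nf >= 3) {
      idx <- which(runif(nf) < tm$outlier_frac)
      # displace only short-gap fixes so a 10x-speed jump stays inside
      # plausible coordinates
      idx <- idx[idx > 1 & c(Inf, gaps)[idx] <= 2]
      for (i in idx) {
        dt <- as.numeric(difftime(tt[i], tt[i - 1], units = "hours"))
        d_deg <- 10 * tm$max_speed * dt / 111
        ang <- runif(1, 0, 2 * pi)
        lon[i] <- lon[i - 1] + d_deg * cos(ang)
        lat[i] <- lat[i - 1] + d_deg * sin(ang)
        out[i] <- TRUE
      }
    }
    tibble(bird_id = sprintf("%s_%02d", stage, b), t = tt,
           lon = lon, lat = lat, stage = stage, outlier = out)
  })
  rows
}

#' Generate smooth gridded fleet effort with interannual trend
#'
#' Each super-fleet gets a fixed Gaussian spatial surface over the 1-degree
#' grid (normalized shares, so annual cell-level effort sums exactly to the
#' annual total) and a deterministic geometric trend in its annual total.
#'
#' @param cfg A [truth_config()].
#' @return Tibble `fleet`, `year`, `cell_lon`, `cell_lat`, `effort`, `unit`.
#' @export
gen_effort <- function(cfg) {
  em <- cfg$effort_model
  set.seed(cfg$seed + 201)
  cells <- grid_cells()
  reg <- ALB_REGION
  map_dfr(names(em$fleets), function(f) {
    fl <- em$fleets[[f]]
    if (is.null(fl$centre)) {
      fl$centre <- c(runif(1, reg[["lon_min"]] + 5, reg[["lon_max"]] - 5),
                     runif(1, reg[["lat_min"]] + 3, reg[["lat_max"]] - 3))
    }
    cx <- fl$centre[1]
    cy <- fl$centre[2]
    w <- exp(-((cells$cell_lon + 0.5 - cx)^2 + (cells$cell_lat + 0.5 - cy)^2) /
               (2 * em$concentration^2))
    w <- w / sum(w)
    keep <- w > 1e-8
    map_dfr(seq_along(em$fishing_years), function(i) {
      tot <- fl$total * (1 + fl$trend)^(i - 1)
      tibble(fleet = f, year = em$fishing_years[i],
             cell_lon = cells$cell_lon[keep], cell_lat = cells$cell_lat[keep],
             effort = tot * w[keep] / sum(w[keep]), unit = fl$unit)
    })
  })
}

#' Generate daily weather and annual SSHA series
#'
#' Daily rainfall and maximum temperature covering every chick-rearing
#' window of the configured span, built so the annual covariates have known
#' structure: chick-window rainfall totals follow an AR(1) process around a
#' linear trend; hot-day counts are Poisson with an AR(1)-perturbed linear
#' mean, realised by placing exactly that many above-threshold days inside
#' the window (all other days stay below 23 degrees C); SSHA is i.i.d.
#' normal per year.
#'
#' @param cfg A [truth_config()].
#' @return List with `weather` (tibble `date`, `rain_mm`, `tmax_c`) and
#'   `ssha` (tibble `year`, `ssha_m`), plus `truth` (tibble `year`,
#'   `rain_total`, `hot_days`) recording the generated annual values.
#' @export
gen_weather <- function(cfg) {
  wm <- cfg$weather_model
  set.seed(cfg$seed + 301)
  years <- cfg_years(cfg)
  ny <- length(years)
  ar1 <- function(n, ar, sd) {
    if (sd == 0) return(rep(0, n))
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd)
    for (i in seq_len(n - 1)) x[i + 1] <- ar * x[i] + sqrt(1 - ar^2) * rnorm(1, 0, sd)
    x
  }
  rain_tot <- pmax(wm$rain_mean + wm$rain_trend * (seq_len(ny) - 1) +
                     ar1(ny, wm$rain_ar, wm$rain_sd), 0)
  hot_lambda <- pmax(wm$hot_mean + wm$hot_trend * (seq_len(ny) - 1) +
                       ar1(ny, wm$hot_ar, wm$hot_sd), 0)
  hot_n <- rpois(ny, hot_lambda)
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
               as.Date(sprintf("%d-12-31", cfg$start_year + cfg$n_years)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  # seasonal maximum-temperature cycle peaking in early February, capped
  # safely below the 23-degree threshold; hot days are overwritten below
  tmax <- pmin(16 + 5 * cos(2 * pi * (doy - 40) / 365.25) + rnorm(length(dates), 0, 1.2), 22.7)
  rain <- rep(0, length(dates))
  for (i in seq_len(ny)) {
    wd <- window_dates(years[i])
    idx <- as.integer(wd - dates[1]) + 1L
    share <- rexp(length(idx))
    rain[idx] <- rain_tot[i] * share / sum(share)
    nh <- min(hot_n[i], length(idx))
    if (nh > 0) {
      hi <- sample(idx, nh)
      tmax[hi] <- 23.3 + rexp(nh, rate = 0.7)
    }
    hot_n[i] <- nh
  }
  # light background drizzle outside chick windows (scaled to the configured
  # rainfall level) so day-of-year climatology, used for gap imputation, is
  # defined everywhere; zero-rain configurations stay exactly zero
  bg_mean <- wm$rain_mean / 120
  if (bg_mean > 0) {
    bg <- rain == 0
    rain[bg] <- rexp(sum(bg), rate = 1 / bg_mean)
  }
  list(
    weather = tibble(date = dates, rain_mm = rain, tmax_c = tmax),
    ssha = tibble(year = years, ssha_m = rnorm(ny, wm$ssha_mean, wm$ssha_sd)),
    truth = tibble(year = years, rain_total = rain_tot, hot_days = hot_n)
  )
}

#' Generate noisy demographic observations from a known-parameter run
#'
#' Takes the expected observation series of a truth model run and applies
#' the likelihood-conjugate observation noise: multiplicative lognormal on
#' counts, additive truncated normal on rates. The monitoring design
#' (which years carry which observation types, pox-year exclusion flags)
#' comes from `cfg$design`. Rates pushed outside [0, 1] are re-truncated
#' (with a warning).
#'
#' @param cfg A [truth_config()].
#' @param run The truth `alb_run` (produced under `cfg$params`).
#' @param forcings The forcings used for the truth run (supplies return
#'   rates, effort and utilisation grids for the bycatch expectation).
#' @return An [observation_set()].
#' @export
gen_observations <- function(cfg, run, forcings) {
  set.seed(cfg$seed + 401)
  ds <- cfg$design
  on <- cfg$obs_noise
  rec <- run$records
  final_year <- cfg$start_year + cfg$n_years - 1
  trunc01 <- function(x, lo = 0.001, hi = 0.999) {
    if (any(x < lo | x > hi)) {
      warn("observation noise pushed a rate outside [0,1]; re-truncated",
           .frequency = "once", .frequency_id = "albipm_obs_trunc")
    }
    pmin(pmax(x, lo), hi)
  }
  # likelihood sigmas stay positive even in noise-free configurations, so a
  # zero-noise dataset remains fittable (optimum exactly at truth)
  s_or <- function(x, fallback) if (x > 0) x else fallback
  # counts: lognormal, the early count with its own (larger) CV
  cy <- c(ds$early_count_year, ds$count_years)
  sig <- c(on$early_cv, rep(on$pairs_cv, length(ds$count_years)))
  e_pairs <- rec$pairs[match(cy, rec$year)]
  pairs_tb <- tibble(year = cy, value = e_pairs * exp(sig * rnorm(length(cy))),
                     sigma = c(s_or(on$early_cv, 0.3),
                               rep(s_or(on$pairs_cv, 0.1), length(ds$count_years))))
  # breeding success: truncated normal; pox seasons get a disease shock and
  # an exclusion flag
  e_bs <- rec$breeding_success[match(ds$bs_years, rec$year)]
  pox <- ds$bs_years %in% ds$pox_years
  e_bs[pox] <- e_bs[pox] * 0.6
  bs_tb <- tibble(year = ds$bs_years,
                  value = trunc01(e_bs + rnorm(length(e_bs), 0, on$bs_sd)),
                  sigma = s_or(on$bs_sd, 0.05), excluded = pox)
  # juvenile survival: noise on the to-age-5 apparent scale, reported on the
  # first-year scale (the likelihood re-applies the 3-year adjustment)
  app <- apparent_juvenile_survival_to5(run, ds$juv_years, final_year)
  juv_tb <- tibble(
    year = ds$juv_years,
    value = trunc01(app$apparent_s5 + rnorm(nrow(app), 0, on$juv_sd), 0.001, 0.999) /
      exp(-3 * run$params$M),
    sigma = s_or(on$juv_sd, 0.05)
  )
  # single adult-survival and bycatch-rate observations
  ad_e <- mean(rec$adult_survival[rec$year %in% ds$adult_window])
  adult <- list(value = trunc01(ad_e + rnorm(1, 0, on$adult_se)),
                sigma = s_or(on$adult_se, 0.0045), window = ds$adult_window)
  bc_e <- expected_bycatch_rate(run, forcings$effort, forcings$utils,
                                fleet = ds$bycatch_fleet, year = ds$bycatch_year)
  bc_sd <- on$bycatch_cv * bc_e
  bycatch <- list(value = max(bc_e + rnorm(1, 0, bc_sd), 0.01 * bc_e),
                  sigma = s_or(bc_sd, 0.5 * bc_e),
                  fleet = ds$bycatch_fleet, year = ds$bycatch_year)
  rr <- forcings$return_rates
  ret_tb <- if (!is.null(rr)) tibble(year = rr$year, value = rr$value) else NULL
  observation_set(pairs = pairs_tb, breeding_success = bs_tb,
                  juvenile_survival = juv_tb, return_rate = ret_tb,
                  adult_survival = adult, bycatch_rate = bycatch)
}

# observed return rates are drawn before the truth run and used as forcing,
# so generator and fitter condition on exactly the same breeding frequencies
gen_return_rates <- function(cfg) {
  set.seed(cfg$seed + 351)
  ds <- cfg$design
  tibble(year = ds$return_years,
         value = pmin(pmax(cfg$params$return_rate +
                             rnorm(length(ds$return_years), 0, cfg$obs_noise$return_sd),
                           0.5), 1))
}

#' Simulate one complete synthetic dataset
#'
#' Runs the whole generator: tracks (filtered and interpolated into
#' utilisation grids), effort surfaces and overlap indices, weather and
#' SSHA (aggregated into standardized covariates), observed return rates,
#' the truth model run, and the noisy observation set.
#'
#' @param cfg A [truth_config()].
#' @param spatial Optional precomputed list `(effort, utils, overlap)` from
#'   a previous simulation with the same spatial settings; reused to avoid
#'   regenerating identical tracks and effort (replicate datasets share the
#'   tracking and effort data, as a real re-analysis would).
#' @return List `cfg`, `obs`, `forcings` (covariates, overlap,
#'   return_rates, effort, utils), `run` (truth run), `truth` (params with
#'   solved Mj), `weather`.
#' @export
simulate_dataset <- function(cfg = truth_config(), spatial = NULL) {
  years <- cfg_years(cfg)
  if (is.null(spatial)) {
    utils <- lapply(c(juvenile = "juvenile", adult = "adult"), function(st) {
      tr <- gen_tracks(cfg, st)
      tr <- filter_fixes(tr, max_speed = cfg$track_model$max_speed)
      tr <- interpolate_track(tr)
      kernel_utility(tr, bandwidth = 1.0, stage = st)
    })
    effort <- gen_effort(cfg)
    overlap <- overlap_series(effort, utils$juvenile, utils$adult)
    spatial <- list(effort = effort, utils = utils, overlap = overlap)
  }
  wx <- gen_weather(cfg)
  covariates <- build_covariates(wx$weather, wx$ssha, years)
  return_rates <- gen_return_rates(cfg)
  forcings <- list(covariates = covariates, overlap = spatial$overlap,
                   return_rates = return_rates, effort = spatial$effort,
                   utils = spatial$utils)
  run <- run_population(cfg$params, forcings, years)
  obs <- gen_observations(cfg, run, forcings)
  list(cfg = cfg, obs = obs, forcings = forcings, run = run,
       truth = run$params, weather = wx)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the generator's outputs in the package's interchange schemas:
#' tracks, effort, weather, SSHA and observations as CSV, and the truth
#' parameters as JSON (requires jsonlite).
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$cfg
  files <- character(0)
  wcsv <- function(x, name) {
    p <- file.path(dir, name)
    write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
  }
  tracks <- bind_rows(gen_tracks(cfg, "juvenile"), gen_tracks(cfg, "adult"))
  wcsv(tibble(bird_id = tracks$bird_id,
              iso8601_utc = format(tracks$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
              lon_dd = tracks$lon, lat_dd = tracks$lat, stage = tracks$stage),
       "tracks.csv")
  wcsv(sim$forcings$effort, "effort.csv")
  wcsv(sim$weather$weather, "weather.csv")
  wcsv(dplyr::rename(sim$weather$ssha, ssha_m = "ssha_m"), "ssha.csv")
  wcsv(as_tibble(sim$obs), "observations.csv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tp <- sim$truth
    truth <- list(M = tp$M, bs0 = tp$bs0, s_max = tp$s_max, z_c = tp$z_c,
                  q = as.list(tp$q), theta = as.list(tp$effect$theta),
                  b = tp$effect$b, h_pre = tp$h_pre, K = tp$K, Mj = tp$Mj)
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  invisible(files)
}
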