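# Shared, lazily-built fixtures. Expensive objects (a synthetic dataset and
# fitted models on it) are computed once and reused across test files.

fixture_env <- new.env(parent = emptyenv())

fixture_cfg <- function() {
  cfg <- truth_config()
  # lighter tracking load than the full study; spatial structure unchanged
  cfg$track_model$fixes_per_bird <- 60
  cfg$track_model$n_birds <- c(juvenile = 6, adult = 15)
  cfg$seed <- 4242
  cfg
}

fixture_years <- function(cfg = fixture_cfg()) {
  seq(cfg$start_year, length.out = cfg$n_years)
}

fixture_sim <- function() {
  if (is.null(fixture_env$sim)) {
    fixture_env$sim <- simulate_dataset(fixture_cfg())
  }
  fixture_env$sim
}

fixture_fit <- function(subset = "RTS") {
  key <- paste0("fit_", subset)
  if (is.null(fixture_env[[key]])) {
    sim <- fixture_sim()
    cfg <- fixture_cfg()
    fixture_env[[key]] <- fit_population(
      sim$obs, sim$forcings, fixture_years(cfg), subset = subset, b = 1,
      base_params = cfg$params, fixed = "z_c", n_starts = 1, seed = 99
    )
  }
  fixture_env[[key]]
}

# simple daily weather table builder
make_weather <- function(dates, rain = 0, tmax = 15) {
  tibble::tibble(date = as.Date(dates), rain_mm = rain, tmax_c = tmax)
}
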