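test_that("season window anchors the model year and the chick-rearing months", {
  w <- season_window(1994)
  expect_equal(w$season_start, as.Date("1994-10-01"))
  expect_equal(w$window_start, as.Date("1995-02-01"))
  expect_equal(w$window_end, as.Date("1995-05-31"))
  # four months of chick rearing
  expect_equal(length(window_dates <- seq(w$window_start, w$window_end, "day")), 120)
  # reconfiguring the window shifts all aggregates consistently
  wx <- make_weather(seq(as.Date("1994-06-01"), as.Date("1995-12-31"), "day"), rain = 1)
  expect_equal(rainfall_total(wx, 1994), 120)
  jan_apr <- rainfall_total(wx, 1994, start_month = 1, end_month = 4, end_day = 30)
  expect_equal(jan_apr, as.numeric(as.Date("1995-04-30") - as.Date("1995-01-01")) + 1)
})

test_that("rainfall totals sum the window and impute gaps with day-of-year means", {
  dd <- seq(as.Date("1990-01-01"), as.Date("1996-12-31"), "day")
  wx <- make_weather(dd, rain = 0)
  expect_equal(rainfall_total(wx, 1992), 0)
  wx$rain_mm[] <- 1
  expect_equal(rainfall_total(wx, 1992), 120)
  # knock out one window day whose day-of-year mean is 2 mm elsewhere
  target <- as.Date("1993-03-10")
  same_doy <- format(dd, "%m-%d") == "03-10" & dd != target
  wx$rain_mm[same_doy] <- 2
  base <- rainfall_total(wx, 1992)
  wx$rain_mm[dd == target] <- NA
  expect_equal(rainfall_total(wx, 1992), base - 1 + 2)
})

test_that("threshold-day counts use a strict 23-degree exceedance", {
  dd <- seq(as.Date("2000-10-01"), as.Date("2001-09-30"), "day")
  wx <- make_weather(dd, tmax = 15)
  wx$tmax_c[wx$date %in% as.Date(c("2001-02-01", "2001-02-02", "2001-02-03"))] <-
    c(22.9, 23.0, 23.1)
  expect_equal(threshold_days(wx, 2000), 1L)
  wx$tmax_c[] <- 30
  expect_equal(threshold_days(wx, 2000), 120L)
})

test_that("standardization centres and scales by the sample sd and is idempotent", {
  s <- standardize_covariate(tibble::tibble(year = 1:3, value = c(1, 2, 3)))
  expect_equal(s$standardized, c(-1, 0, 1))
  expect_equal(s$standardized[s$raw == 2], 0)
  s2 <- standardize_covariate(tibble::tibble(year = 1:3, value = s$standardized))
  expect_equal(s2$standardized, s$standardized)
  expect_error(
    standardize_covariate(tibble::tibble(year = 1:3, value = rep(5, 3))),
    "zero variance"
  )
})

test_that("environmental multiplier follows the sign-preserving exponential form", {
  for (b in c(0.5, 1, 2)) {
    ef <- env_effect(c(rainfall = 0.7, threshold_days = -0.4, ssha = 0.2), b = b)
    expect_equal(env_multiplier(ef, c(rainfall = 0, threshold_days = 0, ssha = 0)), 1)
  }
  e1 <- env_effect(c(rainfall = 0.2), b = 1)
  expect_equal(env_multiplier(e1, c(rainfall = 1)), exp(0.2))
  e2 <- env_effect(c(rainfall = 0.2), b = 2)
  expect_equal(env_multiplier(e2, c(rainfall = -1)), exp(-0.2))
  # monotone in x with the sign of theta, continuous at 0, for every power
  for (b in c(0.5, 1, 2)) {
    ef <- env_effect(c(rainfall = 0.3), b = b)
    xs <- seq(-3, 3, by = 0.25)
    f <- vapply(xs, function(x) env_multiplier(ef, c(rainfall = x)), numeric(1))
    expect_true(all(diff(f) > 0))
    eps <- vapply(c(-1e-8, 1e-8), function(x) env_multiplier(ef, c(rainfall = x)), numeric(1))
    expect_equal(eps, c(1, 1), tolerance = 1e-3)
  }
  # empty covariate set collapses to the covariate-free model exactly
  expect_identical(env_multiplier(env_effect(setNames(numeric(0), character(0))),
                                  c(rainfall = 2)), 1)
})

test_that("rainfall bias correction subtracts the offset and floors at zero", {
  expect_equal(bias_correct_rainfall(200), 138.5)
  expect_equal(bias_correct_rainfall(30), 0)
  expect_equal(bias_correct_rainfall(c(10, 200), offset = 0), c(10, 200))
})

test_that("percentile regression maps modelled averages onto observed maxima exactly for affine pairs", {
  dd <- seq(as.Date("2000-01-01"), as.Date("2002-12-31"), "day")
  set.seed(1)
  avg <- tibble::tibble(date = dd, tavg_c = 12 + 6 * sin(seq_along(dd) / 58) + rnorm(length(dd)))
  obs_same <- tibble::tibble(date = dd, tmax_c = avg$tavg_c)
  cal <- avg_to_max_temperature(avg, obs_same)
  expect_equal(unname(attr(cal, "calibration")), c(0, 1), tolerance = 1e-8)
  expect_equal(cal$tmax_c, avg$tavg_c, tolerance = 1e-8)
  # modelled = observed - 5 exactly: intercept 5, slope 1
  obs_shift <- tibble::tibble(date = dd, tmax_c = avg$tavg_c + 5)
  cal2 <- avg_to_max_temperature(avg, obs_shift)
  expect_equal(unname(attr(cal2, "calibration")), c(5, 1), tolerance = 1e-8)
  # general affine transform recovered exactly
  obs_aff <- tibble::tibble(date = dd, tmax_c = 1.4 * avg$tavg_c + 3.2)
  cal3 <- avg_to_max_temperature(avg, obs_aff)
  expect_equal(cal3$tmax_c, obs_aff$tmax_c, tolerance = 1e-8)
  expect_error(
    avg_to_max_temperature(avg[1:100, ], obs_same[1:100, ]),
    "shorter than one year"
  )
})

test_that("scenario builder handles climate-neutral draws and SSHA scaling", {
  hist <- tibble::tibble(year = 1980:2009, rainfall = 150, threshold_days = 6, ssha = -0.04)
  sc <- build_scenario(hist, 2011:2020, "climate_neutral", seed = 1)
  expect_equal(sc$rainfall, rep(150, 10))
  expect_equal(sc$threshold_days, rep(6, 10))
  expect_equal(sc$ssha, rep(-0.04, 10))
  sc0 <- build_scenario(hist, 2011:2020, "climate_neutral", ssha_multiplier = 0, seed = 1)
  expect_equal(sc0$ssha, rep(-0.04, 10))
  sc3 <- build_scenario(hist, 2011:2020, "climate_neutral", ssha_multiplier = 3, seed = 1)
  expect_equal(sc3$ssha, rep(4 * -0.04, 10))
  ms <- tibble::tibble(year = 2011:2020, rainfall = 100 + 1:10, threshold_days = 11:20)
  scm <- build_scenario(hist, 2011:2020, "climate_model", model_series = ms)
  expect_equal(scm$rainfall, ms$rainfall)
  expect_equal(scm$threshold_days, ms$threshold_days)
})

test_that("future covariates standardize on the historical scale", {
  hist_raw <- tibble::tibble(year = 1980:1999, rainfall = rnorm(20, 150, 30),
                             threshold_days = rpois(20, 7), ssha = rnorm(20, -0.03, 0.04))
  cov <- build_covariates(raw = hist_raw)
  ctr <- attr(cov, "centers"); scl <- attr(cov, "scales")
  fut <- tibble::tibble(year = 2000:2004, rainfall = 400, threshold_days = 30, ssha = 0.1)
  fcov <- build_covariates(raw = fut, centers = ctr, scales = scl)
  expect_equal(fcov$x_rainfall, rep((400 - ctr[["rainfall"]]) / scl[["rainfall"]], 5))
  expect_true(all(fcov$x_threshold_days > max(cov$x_threshold_days)))
})
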