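no_fish_q <- c(trawl = 0, pelagic_longline = 0, demersal_longline = 0)

test_that("initialization scales the first season to the depleted pair count", {
  r1 <- run_population(albatross_params(h_pre = 1), list(), 1942:1944)
  expect_equal(r1$records$pairs[1], 12000)
  r2 <- run_population(albatross_params(h_pre = 400 / 12000), list(), 1942:1944)
  expect_equal(r2$records$pairs[1], 400)
  expect_error(albatross_params(h_pre = 0), "h_pre")
})

test_that("the unfished population sits at carrying capacity and recovers from depletion", {
  r <- run_population(albatross_params(h_pre = 1), list(), 1942:2041)
  expect_lt(max(abs(r$records$pairs / 12000 - 1)), 0.001)
  # breeding success at K equals the pristine anchor bs0
  expect_equal(r$records$breeding_success[1], 0.42, tolerance = 1e-9)
  rd <- run_population(albatross_params(h_pre = 0.2), list(), 1942:2041)
  expect_true(all(diff(rd$records$pairs) > 0))
  expect_true(all(rd$records$pairs < 12000))
})

test_that("monthly stepping conserves individuals and matches the closed form", {
  p <- albatross_params(h_pre = 0.3,
                        q = c(trawl = 1e-4, pelagic_longline = 1e-6, demersal_longline = 1e-7))
  ov <- tidyr::expand_grid(fleet = names(p$q), year = 1950:1960,
                           stage = c("adult", "juvenile"))
  set.seed(2)
  ov$value <- runif(nrow(ov), 10, 60) / ifelse(ov$fleet == "trawl", 1, 0.001)
  cov <- tibble::tibble(year = 1942:1960, x_rainfall = rnorm(19),
                        x_threshold_days = rnorm(19), x_ssha = rnorm(19))
  p$effect <- env_effect(c(rainfall = 0.2, threshold_days = 0.3, ssha = 0.1))
  f <- list(overlap = ov, covariates = cov)
  rf <- run_population(p, f, 1942:1960)
  rm <- run_population(p, f, 1942:1960, monthly = TRUE)
  expect_equal(rm$records$pairs, rf$records$pairs, tolerance = 1e-12)
  expect_equal(rm$records$fledged, rf$records$fledged, tolerance = 1e-9)
  km <- dplyr::arrange(rm$kills, fleet, year, stage)
  kf <- dplyr::arrange(rf$kills, fleet, year, stage)
  expect_equal(km$kills, kf$kills, tolerance = 1e-9)
})

test_that("a monthly step applies competing exponential rates and parent-death coupling", {
  p <- albatross_params(h_pre = 0.5)
  st <- init_population(p, 1950)
  zero <- list(F_adult = no_fish_q, F_juv = no_fish_q, My0 = 0)
  p0 <- p; p0$M <- 0; p0$Mj <- 0
  st0 <- st; st0$params_Mj <- 0
  after0 <- monthly_step(st0, p0, zero)
  expect_equal(after0$J, st0$J)
  expect_equal(after0$B, st0$B)
  expect_equal(after0$C, st0$C)
  expect_equal(after0$month, st0$month + 1L)
  expect_equal(after0$deaths_last, 0)
  # with mortality: chick survival = extrinsic x both parents, and the
  # monthly deaths balance the head count
  frc <- list(F_adult = no_fish_q, F_juv = no_fish_q, My0 = 0.4)
  after <- monthly_step(st, p, frc)
  sa <- exp(-p$M / 12)
  expect_equal(after$C, st$C * exp(-0.4 / 8) * sa^2, tolerance = 1e-12)
  tot <- function(s) sum(s$J) + sum(s$PB) + sum(s$B) + sum(s$NB) + s$C + sum(s$FL)
  expect_equal(tot(st), tot(after) + after$deaths_last, tolerance = 1e-9 * tot(st))
})

test_that("annual adult survival equals exp(-(M + F)) under constant rates", {
  p <- albatross_params(h_pre = 0.5, q = c(trawl = 1e-3, pelagic_longline = 0,
                                           demersal_longline = 0))
  ov <- tibble::tibble(fleet = "trawl", year = 1950, stage = c("adult", "juvenile"),
                       value = c(5, 7))
  r <- run_population(p, list(overlap = ov), 1949:1951)
  expect_equal(r$records$adult_survival[1], exp(-p$M), tolerance = 1e-12)
  expect_equal(r$records$adult_survival[2], exp(-(p$M + 1e-3 * 5)), tolerance = 1e-12)
  expect_equal(r$records$F_juv[2], 1e-3 * 7, tolerance = 1e-12)
})

test_that("sex symmetry holds exactly under symmetric inputs", {
  p <- albatross_params(h_pre = 0.3, q = c(trawl = 1e-4, pelagic_longline = 1e-6,
                                           demersal_longline = 1e-7))
  ov <- tidyr::expand_grid(fleet = names(p$q), year = 1950:1970,
                           stage = c("adult", "juvenile"))
  ov$value <- 30
  r <- run_population(p, list(overlap = ov), 1942:1970)
  st <- r$state
  expect_equal(st$B[[1]], st$B[[2]], tolerance = 1e-12)
  expect_equal(st$NB[[1]], st$NB[[2]], tolerance = 1e-12)
  expect_equal(unname(st$J[1, ]), unname(st$J[2, ]), tolerance = 1e-12)
  expect_equal(unname(st$PB[1, ]), unname(st$PB[2, ]), tolerance = 1e-12)
})

test_that("density-dependent chick mortality anchors at K and compensates below it", {
  p <- albatross_params()
  expect_equal(exp(-chick_mortality(p, 12000)),
               p$bs0 / exp(-2 * p$M * 8 / 12), tolerance = 1e-12)
  s_low <- exp(-chick_mortality(p, 600))
  s_mid <- exp(-chick_mortality(p, 6000))
  s_K <- exp(-chick_mortality(p, 12000))
  expect_true(s_low > s_mid && s_mid > s_K)
  expect_lt(abs(s_low - p$s_max), 0.02)
  # steep shape exponent: no compensation until N approaches K
  p2 <- albatross_params(z_c = 40)
  expect_equal(exp(-chick_mortality(p2, 6000)), p2$s_max, tolerance = 1e-3)
  # environmental multiplier scales the rate
  expect_equal(chick_mortality(p, 8000, env_mult = 1.7),
               1.7 * chick_mortality(p, 8000), tolerance = 1e-12)
  # above K the soft ceiling pushes survival below the anchor
  expect_lt(suppressWarnings(exp(-chick_mortality(p, 13000))), s_K)
})

test_that("the run's chick mortality matches the exported pieces", {
  p <- albatross_params(h_pre = 0.4,
                        effect = env_effect(c(rainfall = 0.25, ssha = -0.1), b = 2))
  cov <- tibble::tibble(year = 1950:1955, x_rainfall = c(-1.2, 0, 2, 0.5, -0.3, 1),
                        x_threshold_days = 0, x_ssha = c(0.4, -1, 0, 2, 1, -2))
  r <- run_population(p, list(covariates = cov), 1950:1955)
  for (i in seq_len(6)) {
    x <- c(rainfall = cov$x_rainfall[i], threshold_days = 0, ssha = cov$x_ssha[i])
    m <- env_multiplier(p$effect, x)
    expect_equal(r$records$env_mult[i], m, tolerance = 1e-12)
    expect_equal(r$records$My0[i],
                 chick_mortality(r$params, r$records$pairs[i], m), tolerance = 1e-12)
  }
})

test_that("recruitment machinery reproduces the printed ogive increments", {
  og <- maturity_ogive()
  rho <- albipm:::ogive_rho(og)
  # fraction of a cohort first breeding at age a (no mortality) = ogive step
  surv_unrec <- cumprod(c(1, 1 - rho[-length(rho)]))
  frac <- surv_unrec * rho
  expect_equal(unname(frac), diff(c(0, og$p_first_breeding)), tolerance = 1e-12)
  # mean age at first breeding from the printed increments (hand sum: 9.66)
  expect_equal(sum(og$age * unname(frac)), 9.66, tolerance = 1e-9)
})

test_that("bycatch accounting is attributable and linear at small rates", {
  q <- c(trawl = 5e-5, pelagic_longline = 1e-6, demersal_longline = 0)
  p <- albatross_params(h_pre = 0.4, q = q)
  ov <- tidyr::expand_grid(fleet = names(q), year = 1960:1980,
                           stage = c("adult", "juvenile"))
  ov$value <- ifelse(ov$fleet == "trawl", 40, 3000)
  r <- run_population(p, list(overlap = ov), 1942:1980)
  k <- dplyr::count(r$kills, fleet, wt = kills)
  expect_false("demersal_longline" %in% k$fleet)   # q = 0 -> exactly no kills
  # switching one fleet off reduces total deaths by about its kill total
  p0 <- p; p0$q[["pelagic_longline"]] <- 0
  r0 <- run_population(p0, list(overlap = ov), 1942:1980)
  expect_false("pelagic_longline" %in% r0$kills$fleet)
  expect_gt(sum(r0$records$pairs), sum(r$records$pairs))
})

test_that("expected bycatch rate is zero without catchability and ~doubles with q", {
  sim <- fixture_sim()
  run <- sim$run
  eff <- sim$forcings$effort
  utils <- sim$forcings$utils
  rate <- expected_bycatch_rate(run, eff, utils, "trawl", 2006)
  expect_gt(rate, 0)
  p0 <- run$params; p0$q[["trawl"]] <- 0
  r0 <- run_population(p0, sim$forcings, fixture_years())
  expect_equal(expected_bycatch_rate(r0, eff, utils, "trawl", 2006), 0)
  # doubling q at (effectively) fixed state: fish only in the rate year, so
  # the population entering 2006 is identical under q and 2q
  f1 <- sim$forcings
  f1$overlap <- f1$overlap[f1$overlap$year == 2006, ]
  p1 <- run$params
  p2 <- run$params; p2$q[["trawl"]] <- 2 * p2$q[["trawl"]]
  r1 <- run_population(p1, f1, fixture_years())
  r2 <- run_population(p2, f1, fixture_years())
  ratio <- expected_bycatch_rate(r2, eff, utils, "trawl", 2006) /
    expected_bycatch_rate(r1, eff, utils, "trawl", 2006)
  expect_gt(ratio, 1.95)
  expect_lt(ratio, 2.0 + 1e-9)
})

test_that("apparent juvenile survival reflects incomplete recruitment", {
  sim <- fixture_sim()
  run <- sim$run
  og <- run$params$ogive
  js <- juvenile_survival_expected(run, c(1980, 1995, 2002, 2010))
  # old cohort: apparent equals true survival to age 5
  app <- apparent_juvenile_survival_to5(run, c(1980, 1995, 2002, 2010), 2010)
  expect_equal(app$apparent_s5[1], js$s_to5[1])
  # final-year cohort: no time to recruit
  expect_equal(app$apparent_s5[4], 0)
  # mid-horizon cohorts: year-by-year recruitment enumeration oracle
  dg <- diff(c(0, og$p_first_breeding))
  for (k in 2:3) {
    cohort <- app$year[k]
    reachable <- og$age + cohort <= 2010
    expect_equal(app$apparent_s5[k], js$s_to5[k] * sum(dg[reachable]),
                 tolerance = 1e-12)
  }
  # the 3-adult-year adjustment ties first-year and to-age-5 survival when
  # no fishing overlies the later juvenile years
  r_nf <- run_population(albatross_params(h_pre = 0.4), list(), 1950:1990)
  js_nf <- juvenile_survival_expected(r_nf, 1960)
  expect_equal(js_nf$s_to5 / js_nf$s_first, exp(-3 * r_nf$params$M), tolerance = 1e-12)
})

test_that("infeasible life cycles are refused", {
  expect_error(init_population(albatross_params(bs0 = 0.05, s_max = 0.2)),
               "cannot replace itself")
})
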