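test_that("the composite likelihood decomposes additively by observation type", {
  sim <- fixture_sim()
  cfg <- fixture_cfg()
  years <- fixture_years()
  nll <- neg_log_lik(cfg$params, sim$obs, sim$forcings, years)
  comp <- attr(nll, "components")
  expect_equal(sum(comp), as.numeric(nll), tolerance = 1e-12)
  expect_true(all(c("pairs", "breeding_success", "juvenile_survival",
                    "adult_survival", "bycatch_rate") %in% names(comp)))
  # independent recomputation of the pairs component from the run records
  run <- run_population(cfg$params, sim$forcings, years)
  obs_p <- sim$obs[sim$obs$type == "pairs", ]
  e <- run$records$pairs[match(obs_p$year, run$records$year)]
  by_hand <- sum(0.5 * ((log(obs_p$value) - log(e)) / obs_p$sigma)^2 +
                   log(obs_p$sigma) + 0.5 * log(2 * pi) + log(obs_p$value))
  expect_equal(unname(comp["pairs"]), by_hand, tolerance = 1e-10)
  # breeding-success component recomputed the same way (excluding pox years)
  obs_b <- sim$obs[sim$obs$type == "breeding_success" & !sim$obs$excluded, ]
  eb <- run$records$breeding_success[match(obs_b$year, run$records$year)]
  bh <- sum(0.5 * ((obs_b$value - eb) / obs_b$sigma)^2 + log(obs_b$sigma) +
              0.5 * log(2 * pi))
  expect_equal(unname(comp["breeding_success"]), bh, tolerance = 1e-10)
})

test_that("excluded pox years contribute exactly nothing", {
  sim <- fixture_sim()
  cfg <- fixture_cfg()
  years <- fixture_years()
  nll0 <- as.numeric(neg_log_lik(cfg$params, sim$obs, sim$forcings, years))
  pert <- sim$obs
  i <- which(pert$excluded)
  expect_gt(length(i), 0)
  pert$value[i] <- pert$value[i] * 5 + 0.1
  nll1 <- as.numeric(neg_log_lik(cfg$params, pert, sim$forcings, years))
  expect_identical(nll1, nll0)
  # observation order does not matter either
  shuf <- sim$obs[sample(nrow(sim$obs)), ]
  attributes(shuf)[c("adult_window", "bycatch_meta")] <-
    attributes(sim$obs)[c("adult_window", "bycatch_meta")]
  expect_equal(as.numeric(neg_log_lik(cfg$params, shuf, sim$forcings, years)),
               nll0, tolerance = 1e-10)
})

test_that("inflating an observation's SE at fixed large residual lowers its cost", {
  sim <- fixture_sim()
  cfg <- fixture_cfg()
  years <- fixture_years()
  obs <- sim$obs
  i <- which(obs$type == "pairs")[2]
  obs$value[i] <- obs$value[i] * 1.8   # force a large residual
  c1 <- attr(neg_log_lik(cfg$params, obs, sim$forcings, years), "components")
  obs2 <- obs
  obs2$sigma[i] <- 2 * obs2$sigma[i]
  c2 <- attr(neg_log_lik(cfg$params, obs2, sim$forcings, years), "components")
  expect_lt(c2[["pairs"]], c1[["pairs"]])
})

test_that("out-of-bounds parameters are penalised with an infinite likelihood", {
  sim <- fixture_sim()
  p <- fixture_cfg()$params
  p$M <- 0.9
  expect_identical(as.numeric(neg_log_lik(p, sim$obs, sim$forcings, fixture_years())),
                   Inf)
})

test_that("fitting noise-free observations recovers the generating parameters", {
  cfg <- fixture_cfg()
  cfg$obs_noise <- list(pairs_cv = 0, early_cv = 0, bs_sd = 0, juv_sd = 0,
                        adult_se = 0, bycatch_cv = 0, return_sd = 0)
  sim <- simulate_dataset(cfg)
  # zero CVs: observations equal expectations exactly
  rec <- sim$run$records
  obs_p <- sim$obs[sim$obs$type == "pairs", ]
  expect_equal(obs_p$value, rec$pairs[match(obs_p$year, rec$year)], tolerance = 1e-12)
  obs_b <- sim$obs[sim$obs$type == "breeding_success" & !sim$obs$excluded, ]
  expect_equal(obs_b$value,
               rec$breeding_success[match(obs_b$year, rec$year)], tolerance = 1e-12)
  expect_true(all(sim$obs$sigma[sim$obs$type != "return_rate"] > 0))
  # truth attains the minimum: no fitted start beats it by more than tolerance
  nll_truth <- as.numeric(neg_log_lik(cfg$params, sim$obs, sim$forcings, fixture_years()))
  fit <- fit_population(sim$obs, sim$forcings, fixture_years(), subset = "RTS",
                        b = 1, base_params = cfg$params, fixed = "z_c",
                        n_starts = 1, seed = 5)
  expect_lte(fit$nll, nll_truth + 0.01)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[["M"]], cfg$params$M, tolerance = 0.02)
  expect_equal(est[["bs0"]], cfg$params$bs0, tolerance = 0.02)
  expect_equal(est[["theta_threshold_days"]],
               cfg$params$effect$theta[["threshold_days"]], tolerance = 0.02)
})

test_that("pox seasons are flagged and excluded in generated observations", {
  sim <- fixture_sim()
  cfg <- fixture_cfg()
  bs <- sim$obs[sim$obs$type == "breeding_success", ]
  expect_setequal(bs$year[bs$excluded], cfg$design$pox_years)
})

test_that("model comparison reproduces likelihood-ratio arithmetic", {
  fake <- function(subset, nll) {
    structure(list(subset = subset, b = 1, nll = nll,
                   k = 5 + length(albipm:::parse_subset(subset)), convergence = 0),
              class = "alb_fit")
  }
  fits <- list(fake("xxx", 292.3), fake("RTS", 251.7), fake("xTx", 292.3))
  cmp <- compare_models(fits)
  expect_equal(cmp$model, c("RTS", "xxx", "xTx")[order(c(251.7, 292.3, 292.3))])
  rts <- cmp[cmp$model == "RTS", ]
  expect_equal(rts$stat, 2 * (292.3 - 251.7))
  expect_equal(rts$df, 3)
  expect_lt(rts$p, 1e-16)
  expect_equal(rts$AIC, 2 * 251.7 + 2 * 8)
  # identical likelihood with one added parameter: statistic 0, p = 1
  xtx <- cmp[cmp$model == "xTx", ]
  expect_equal(xtx$stat, 0)
  expect_equal(xtx$p, 1)
  expect_true(is.na(cmp$stat[cmp$model == "xxx"]))
})

test_that("nested covariate models are ordered and LRT statistics non-negative", {
  f_rts <- fixture_fit("RTS")
  f_xts <- fixture_fit("xTS")
  f_xxx <- fixture_fit("xxx")
  expect_lte(f_rts$nll, f_xts$nll + 1e-4)
  expect_lte(f_xts$nll, f_xxx$nll + 1e-4)
  cmp <- compare_models(list(f_rts, f_xts, f_xxx))
  expect_true(all(cmp$stat[!is.na(cmp$stat)] >= -1e-4))
  expect_true(all(diff(cmp$neg_log_lik) >= 0))
  # the generating model includes all three covariates; their joint inclusion
  # should be strongly supported on this dataset
  expect_lt(cmp$p[cmp$model == "RTS"], 0.01)
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fixture_fit("RTS")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error"))
  expect_true(all(c("M", "bs0", "q_trawl", "theta_rainfall") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$AIC, 2 * fit$nll + 2 * fit$k)
  expect_equal(gl$convergence, 0)
})

test_that("sensitivity runs move catchability with the bycatch observation", {
  fit <- fixture_fit("RTS")
  sens <- sensitivity_suite(fit, bycatch_factors = c(0.5, 2))
  est <- sens$estimates
  q_base <- est$estimate[est$case == "baseline" & est$term == "q_trawl"]
  q_half <- est$estimate[est$case == "bycatch_x0.5" & est$term == "q_trawl"]
  q_dbl <- est$estimate[est$case == "bycatch_x2" & est$term == "q_trawl"]
  expect_lt(q_half, q_base)
  expect_gt(q_dbl, q_base)
  k <- sens$kills
  k_base <- sum(k$total_kills[k$case == "baseline" & k$fleet == "trawl"])
  k_half <- sum(k$total_kills[k$case == "bycatch_x0.5" & k$fleet == "trawl"])
  expect_lt(k_half / k_base, 0.95)
  expect_gt(k_half / k_base, 0.25)
  # the early-count case perturbs the earliest pairs observation only
  expect_true("early_count_low" %in% est$case)
})
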