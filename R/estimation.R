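#' Assemble an observation set for the composite likelihood
#'
#' Collects the monitoring observations the model is conditioned on into one
#' long table. Error models by type: counts of breeding `pairs` are
#' lognormal (`sigma` = sd on the log scale, roughly a CV); rate
#' observations (`breeding_success`, `juvenile_survival`, `adult_survival`,
#' `bycatch_rate`) are normal with `sigma` the standard error. Rows with
#' `excluded = TRUE` (pox-outbreak breeding seasons) contribute exactly
#' nothing to the likelihood. `return_rate` rows are inputs to the dynamics
#' (breeding frequency), not likelihood components.
#'
#' Juvenile-survival observations are first-year (to age 1) survival rates;
#' the likelihood adjusts them to survival to age 5 by adding three years of
#' adult natural mortality and compares them with the model's apparent
#' survival to age 5, which accounts for incomplete recruitment of recent
#' cohorts. `sigma` for those rows is on the adjusted (to-age-5) scale.
#'
#' @param pairs,breeding_success,juvenile_survival,return_rate Tibbles with
#'   `year`, `value`, and optionally `sigma` and `excluded`.
#' @param adult_survival List `value`, `sigma`, `window` (years whose mean
#'   model survival it is compared with).
#' @param bycatch_rate List `value`, `sigma`, `fleet`, `year`, plus
#'   optionally `region`.
#' @param default_sigma Named vector of per-type default sigmas used where a
#'   row has none.
#' @return An `alb_obs` tibble: `type`, `year`, `value`, `sigma`,
#'   `excluded`, with attributes `adult_window` and `bycatch_meta`.
#' @export
observation_set <- function(pairs = NULL, breeding_success = NULL,
                            juvenile_survival = NULL, return_rate = NULL,
                            adult_survival = NULL, bycatch_rate = NULL,
                            default_sigma = c(pairs = 0.1, breeding_success = 0.05,
                                              juvenile_survival = 0.10,
                                              adult_survival = 0.0045,
                                              bycatch_rate = NA, return_rate = NA)) {
  row_of <- function(tb, type) {
    if (is.null(tb)) return(NULL)
    tb <- as_tibble(tb)
    if (!"sigma" %in% names(tb)) tb$sigma <- NA_real_
    if (!"excluded" %in% names(tb)) tb$excluded <- FALSE
    tb$sigma[is.na(tb$sigma)] <- default_sigma[[type]]
    tibble(type = type, year = tb$year, value = tb$value,
           sigma = tb$sigma, excluded = tb$excluded)
  }
  out <- bind_rows(
    row_of(pairs, "pairs"),
    row_of(breeding_success, "breeding_success"),
    row_of(juvenile_survival, "juvenile_survival"),
    row_of(return_rate, "return_rate")
  )
  if (!is.null(adult_survival)) {
    out <- bind_rows(out, tibble(
      type = "adult_survival", year = NA_integer_,
      value = adult_survival$value,
      sigma = adult_survival$sigma %||% default_sigma[["adult_survival"]],
      excluded = FALSE
    ))
  }
  meta <- NULL
  if (!is.null(bycatch_rate)) {
    out <- bind_rows(out, tibble(
      type = "bycatch_rate", year = bycatch_rate$year,
      value = bycatch_rate$value,
      sigma = bycatch_rate$sigma %||% (0.5 * bycatch_rate$value),
      excluded = FALSE
    ))
    meta <- bycatch_rate[c("fleet", "year")]
    meta$region <- bycatch_rate$region %||% ALB_BYCATCH_REGION
  }
  out <- filter(out, !is.na(.data$value))
  attr(out, "adult_window") <- adult_survival$window %||% NULL
  attr(out, "bycatch_meta") <- meta
  class(out) <- c("alb_obs", class(out))
  out
}

ln_norm <- function(resid, sigma) {
  0.5 * (resid / sigma)^2 + log(sigma) + 0.5 * log(2 * pi)
}

#' Composite negative log-likelihood
#'
#' Sum of the per-type components described in [observation_set()]:
#' lognormal for counts, normal for rates, normal with a deliberately large
#' standard error for the single bycatch-rate datum, pox-flagged
#' breeding-success years skipped. Parameters outside their bounds return
#' `Inf`.
#'
#' @param params An [albatross_params()].
#' @param obs An [observation_set()].
#' @param forcings Forcings list as in [run_population()], plus `effort` and
#'   `utils` (needed for the bycatch-rate expectation).
#' @param years Model years to simulate (must cover the observations).
#' @param final_year Final data year for the recruitment-truncation of
#'   juvenile survival (default: max observation year).
#' @return Scalar negative log-likelihood with attribute `components`
#'   (named per-type vector summing to the total).
#' @export
neg_log_lik <- function(params, obs, forcings, years,
                        final_year = max(obs$year, na.rm = TRUE)) {
  if (!param_in_bounds(params)) return(structure(Inf, components = NULL))
  run <- try(run_population(params, forcings, years), silent = TRUE)
  if (inherits(run, "try-error")) return(structure(Inf, components = NULL))
  neg_log_lik_run(run, obs, forcings, final_year)
}

# likelihood given an already-computed run (shared by neg_log_lik and fit)
neg_log_lik_run <- function(run, obs, forcings, final_year) {
  rec <- run$records
  comp <- c(pairs = 0, breeding_success = 0, juvenile_survival = 0,
            adult_survival = 0, bycatch_rate = 0)
  use <- obs[!obs$excluded & obs$type != "return_rate", ]
  # counts: lognormal
  o <- use[use$type == "pairs", ]
  if (nrow(o) > 0) {
    e <- rec$pairs[match(o$year, rec$year)]
    comp["pairs"] <- sum(ln_norm(log(o$value) - log(e), o$sigma) + log(o$value))
  }
  o <- use[use$type == "breeding_success", ]
  if (nrow(o) > 0) {
    e <- rec$breeding_success[match(o$year, rec$year)]
    comp["breeding_success"] <- sum(ln_norm(o$value - e, o$sigma))
  }
  o <- use[use$type == "juvenile_survival", ]
  if (nrow(o) > 0) {
    app <- apparent_juvenile_survival_to5(run, o$year, final_year)
    adj <- o$value * exp(-3 * run$params$M)
    comp["juvenile_survival"] <- sum(ln_norm(adj - app$apparent_s5, o$sigma))
  }
  o <- use[use$type == "adult_survival", ]
  if (nrow(o) > 0) {
    w <- attr(obs, "adult_window") %||% rec$year
    e <- mean(rec$adult_survival[rec$year %in% w])
    comp["adult_survival"] <- sum(ln_norm(o$value - e, o$sigma))
  }
  o <- use[use$type == "bycatch_rate", ]
  if (nrow(o) > 0) {
    meta <- attr(obs, "bycatch_meta")
    e <- expected_bycatch_rate(run, forcings$effort, forcings$utils,
                               fleet = meta$fleet, year = meta$year,
                               region = meta$region)
    comp["bycatch_rate"] <- sum(ln_norm(o$value - e, o$sigma))
  }
  structure(sum(comp), components = comp)
}

param_in_bounds <- function(p) {
  ok <- p$M > 0 && p$M < 0.5 &&
    p$bs0 > 0.01 && p$bs0 < 0.99 &&
    p$z_c > 0.005 && p$z_c < 50 &&
    all(p$q >= 0) && all(abs(p$effect$theta) <= 10) &&
    s_K(p) < p$s_max
  isTRUE(ok)
}

# --- parameter transforms ---------------------------------------------------
# terms live on an unconstrained scale: log for positive quantities, logit
# for bs0, identity for covariate slopes
covariate_of <- c(R = "rainfall", T = "threshold_days", S = "ssha")

parse_subset <- function(subset) {
  keys <- strsplit(gsub("x", "", subset), "")[[1]]
  unname(covariate_of[keys[keys %in% names(covariate_of)]])
}

term_transforms <- function(term) {
  if (term %in% c("M", "z_c") || grepl("^q_", term)) {
    list(to = log, from = exp, dfrom = exp)
  } else if (term == "bs0") {
    list(to = stats::qlogis, from = stats::plogis,
         dfrom = function(u) stats::plogis(u) * (1 - stats::plogis(u)))
  } else {
    list(to = identity, from = identity, dfrom = function(u) rep(1, length(u)))
  }
}

q_name_of <- c(q_trawl = "trawl", q_pelagic = "pelagic_longline",
               q_demersal = "demersal_longline")

apply_par <- function(base, u, terms, tie_demersal = TRUE) {
  p <- base
  th <- p$effect$theta
  for (i in seq_along(terms)) {
    tm <- terms[i]
    val <- term_transforms(tm)$from(u[i])
    if (tm %in% c("M", "bs0", "z_c", "h_pre")) {
      p[[tm]] <- val
    } else if (tm %in% names(q_name_of)) {
      p$q[[q_name_of[[tm]]]] <- val
    } else if (grepl("^theta_", tm)) {
      th[[sub("^theta_", "", tm)]] <- val
    }
  }
  if (tie_demersal && !"q_demersal" %in% terms) {
    p$q[["demersal_longline"]] <- p$q[["pelagic_longline"]]
  }
  p$effect <- env_effect(th, b = p$effect$b)
  p
}

extract_par <- function(params, terms) {
  vapply(terms, function(tm) {
    v <- if (tm %in% c("M", "bs0", "z_c", "h_pre")) {
      params[[tm]]
    } else if (tm %in% names(q_name_of)) {
      params$q[[q_name_of[[tm]]]]
    } else {
      params$effect$theta[[sub("^theta_", "", tm)]]
    }
    term_transforms(tm)$to(v)
  }, numeric(1))
}

#' Fit the integrated population model
#'
#' Maximises the composite likelihood over the free parameters (adult
#' natural mortality M, pristine breeding success bs0, density-dependence
#' shape z_c, trawl and pelagic-longline catchabilities, and one slope theta
#' per included covariate; demersal-longline catchability is tied to
#' pelagic by default). Parameters are log- or logit-transformed to an
#' unconstrained scale and optimised by BFGS from `n_starts` jittered
#' starting points; standard errors come from the inverse curvature at the
#' optimum (delta method back to the natural scale). Ties across starts
#' break by lowest negative log-likelihood, then lowest parameter norm.
#'
#' @param obs An [observation_set()].
#' @param forcings Forcings list (see [neg_log_lik()]).
#' @param years Model years to simulate.
#' @param subset Covariate subset label: characters `R` (rainfall), `T`
#'   (threshold days), `S` (SSHA), `x` for exclusion — `"RTS"`, `"xTS"`,
#'   ..., `"xxx"`.
#' @param b Power of the environmental response (0.5, 1 or 2).
#' @param base_params Baseline [albatross_params()] supplying fixed values.
#' @param start Optional named start values on the natural scale.
#' @param fixed Character vector of default-free terms to fix at their
#'   `base_params`/`start` values (e.g. `"z_c"`).
#' @param n_starts Number of optimisation starts (first is the documented
#'   default start; the rest are jittered).
#' @param jitter_sd Jitter sd on the transformed scale.
#' @param seed Seed for the jittered starts.
#' @return An `alb_fit`.
#' @export
fit_population <- function(obs, forcings, years, subset = "RTS", b = 1,
                           base_params = albatross_params(), start = NULL,
                           fixed = NULL, n_starts = 5, jitter_sd = 0.3,
                           seed = 1) {
  stopifnot(b %in% c(0.5, 1, 2))
  covs <- parse_subset(subset)
  base <- base_params
  base$effect <- env_effect(setNames(rep(0, length(covs)), covs), b = b)
  terms <- c("M", "bs0", "z_c", "q_trawl", "q_pelagic",
             if (length(covs)) paste0("theta_", covs))
  terms <- setdiff(terms, fixed)
  # documented default start: mid-range demography, catchability sized so the
  # mean overlap index translates to F ~ 0.01 per year, slopes at zero
  ov <- forcings$overlap
  q0 <- function(fleet) {
    v <- ov$value[ov$fleet == fleet & ov$stage == "adult"]
    if (length(v) == 0 || mean(v) == 0) 1e-6 else 0.01 / mean(v)
  }
  start_def <- list(M = 0.05, bs0 = 0.5, z_c = 1,
                    q_trawl = q0("trawl"), q_pelagic = q0("pelagic_longline"))
  for (cv in covs) start_def[[paste0("theta_", cv)]] <- 0
  if (!is.null(start)) start_def[names(start)] <- start
  # fixed terms stay at base_params values unless explicitly given in `start`
  for (tm in intersect(names(start %||% list()), fixed)) {
    base <- apply_par(base, term_transforms(tm)$to(start[[tm]]), tm)
  }
  u0 <- vapply(terms, function(tm) term_transforms(tm)$to(start_def[[tm]]), numeric(1))
  final_year <- max(obs$year, na.rm = TRUE)
  objective <- function(u) {
    p <- apply_par(base, u, terms)
    v <- neg_log_lik(p, obs, forcings, years, final_year)
    if (!is.finite(v)) 1e10 else as.numeric(v)
  }
  set.seed(seed)
  starts <- c(list(u0), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
    u0 + rnorm(length(u0), 0, jitter_sd)
  }))
  fits <- lapply(starts, function(u) {
    tryCatch(
      optim(u, objective, method = "BFGS",
            control = list(reltol = 1e-9, maxit = 400)),
      error = function(e) list(value = Inf, par = u, convergence = 99)
    )
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  nrm <- vapply(fits, function(f) sum(f$par^2), numeric(1))
  best <- fits[[order(vals, nrm)[1]]]
  H <- try(optimHess(best$par, objective), silent = TRUE)
  se_u <- rep(NA_real_, length(terms))
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error")) {
      dg <- diag(Vi)
      se_u <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  est_nat <- vapply(seq_along(terms), function(i) {
    term_transforms(terms[i])$from(best$par[i])
  }, numeric(1))
  se_nat <- vapply(seq_along(terms), function(i) {
    abs(term_transforms(terms[i])$dfrom(best$par[i])) * se_u[i]
  }, numeric(1))
  p_hat <- apply_par(base, best$par, terms)
  run_hat <- run_population(p_hat, forcings, years)
  structure(list(
    estimates = tibble(term = terms, estimate = est_nat, std_error = se_nat,
                       u = best$par, se_u = se_u),
    params_hat = run_hat$params,
    nll = best$value,
    k = length(terms),
    subset = subset, b = b,
    convergence = best$convergence,
    run = run_hat,
    obs = obs, forcings = forcings, years = years,
    n_starts = n_starts, seed = seed, start = start_def
  ), class = "alb_fit")
}

#' @method tidy alb_fit
#' @export
tidy.alb_fit <- function(x, ...) x$estimates[, c("term", "estimate", "std_error")]

#' @method glance alb_fit
#' @export
glance.alb_fit <- function(x, ...) {
  tibble(subset = x$subset, b = x$b, neg_log_lik = x$nll, k = x$k,
         AIC = 2 * x$nll + 2 * x$k, convergence = x$convergence)
}

#' @export
print.alb_fit <- function(x, ...) {
  cat("<alb_fit> covariates:", x$subset, " b =", x$b,
      " -lnL =", round(x$nll, 2), "\n")
  print(tidy(x))
  invisible(x)
}

#' Likelihood-ratio comparison of covariate models
#'
#' For each fitted covariate subset, the improvement over the
#' covariate-free null model (`xxx`) is `2 x (lnL - lnL_null)`, compared
#' with a chi-square on the number of added slope parameters; AIC is
#' `2 x (-lnL) + 2 x k` from unrounded likelihoods. Rows are ordered by
#' negative log-likelihood (best first).
#'
#' @param fits List of `alb_fit` objects, including the null (`xxx`).
#' @return Tibble `model`, `neg_log_lik`, `stat`, `df`, `p`, `AIC`.
#' @export
compare_models <- function(fits) {
  gl <- map_dfr(fits, function(f) {
    g <- glance(f)
    g$n_theta <- length(parse_subset(f$subset))
    g
  })
  null_i <- which(gl$n_theta == 0)
  if (length(null_i) != 1) abort("exactly one covariate-free (xxx) fit is required")
  nll0 <- gl$neg_log_lik[null_i]
  out <- gl %>%
    mutate(
      model = .data$subset,
      stat = 2 * (nll0 - .data$neg_log_lik),
      df = .data$n_theta,
      p = pchisq(.data$stat, .data$df, lower.tail = FALSE)
    ) %>%
    arrange(.data$neg_log_lik) %>%
    select("model", "neg_log_lik", "stat", "df", "p", "AIC")
  out$stat[out$model == gl$subset[null_i]] <- NA_real_
  out$df[out$model == gl$subset[null_i]] <- NA_integer_
  out$p[out$model == gl$subset[null_i]] <- NA_real_
  out
}

#' Sensitivity of the fit to fragile observations
#'
#' Re-fits the model under perturbed observation sets: the early (1972-type)
#' breeding-pair count replaced by a lower alternative, and the single
#' bycatch-rate observation halved and doubled. Each case warm-starts from
#' the baseline optimum. Reports parameter estimates and per-fleet total
#' kills per case alongside the baseline.
#'
#' @param fit A baseline `alb_fit`.
#' @param early_count_alt Replacement value for the earliest pairs count
#'   (default 1500/2300 of it).
#' @param bycatch_factors Multipliers applied to the bycatch observation.
#' @return List with `estimates` (tibble case x term with deltas) and
#'   `kills` (tibble case x fleet total kills).
#' @export
sensitivity_suite <- function(fit, early_count_alt = NULL,
                              bycatch_factors = c(0.5, 2)) {
  obs <- fit$obs
  cases <- list(baseline = obs)
  pr <- obs$type == "pairs"
  if (any(pr)) {
    y0 <- min(obs$year[pr])
    alt <- obs
    i <- which(pr & obs$year == y0)
    alt$value[i] <- early_count_alt %||% (obs$value[i] * 1500 / 2300)
    cases[["early_count_low"]] <- alt
  }
  bc <- obs$type == "bycatch_rate"
  for (f in bycatch_factors) {
    alt <- obs
    alt$value[bc] <- obs$value[bc] * f
    alt$sigma[bc] <- obs$sigma[bc] * f
    cases[[paste0("bycatch_x", f)]] <- alt
  }
  warm <- setNames(as.list(fit$estimates$estimate), fit$estimates$term)
  fixed_terms <- setdiff(c("M", "bs0", "z_c", "q_trawl", "q_pelagic",
                           paste0("theta_", parse_subset(fit$subset))),
                         fit$estimates$term)
  res <- imap(cases, function(ob, nm) {
    if (nm == "baseline") return(fit)
    fit_population(ob, fit$forcings, fit$years, subset = fit$subset, b = fit$b,
                   base_params = fit$params_hat, start = warm,
                   fixed = fixed_terms, n_starts = 1, seed = fit$seed)
  })
  est <- map_dfr(res, tidy, .id = "case")
  base_est <- setNames(fit$estimates$estimate, fit$estimates$term)
  est$delta_pct <- 100 * (est$estimate / base_est[est$term] - 1)
  kills <- map_dfr(res, function(f) {
    f$run$kills %>% group_by(.data$fleet) %>%
      summarise(total_kills = sum(.data$kills), .groups = "drop")
  }, .id = "case")
  list(estimates = est, kills = kills)
}
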