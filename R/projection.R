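#' Project the fitted population forward under a scenario
#'
#' Continues the fitted trajectory from its final state to `end_year`.
#' Future fishing effort is held at the mean overlap of the last five data
#' years per fleet and stage, scaled by `1 - mitigation` for the trawl
#' fleet (or all fleets). Future covariates come from `scenario` (a tibble
#' of raw annual values) or, when `scenario = NULL`, from climate-neutral
#' draws (normal with the historical mean and variance). Future values are
#' standardized with the historical centre and scale, so they can fall
#' outside the historical range. Breeding frequency reverts to its default.
#'
#' @param fit An `alb_fit`.
#' @param scenario Optional tibble `year`, `rainfall`, `threshold_days`,
#'   `ssha` covering the future years (e.g. a bias-corrected climate-model
#'   series); `NULL` for climate-neutral draws.
#' @param mitigation Fraction of bycatch removed, in [0, 1].
#' @param all_fleets Apply mitigation to every fleet instead of trawl only.
#' @param ssha_multiplier Optional m: future SSHA fixed at (1 + m) x the
#'   historic mean anomaly (overrides the scenario's SSHA column).
#' @param end_year Final projected year.
#' @param n_draws Number of stochastic replicates (climate-neutral source;
#'   a deterministic scenario is simply repeated).
#' @param seed Integer seed; draw j uses `seed + j`.
#' @return An `alb_projection`: `draws` tibble (`draw`, `year`, `pairs`,
#'   `breeding_success`) plus the projection settings.
#' @export
project_population <- function(fit, scenario = NULL, mitigation = 0,
                               all_fleets = FALSE, ssha_multiplier = NULL,
                               end_year = 2100, n_draws = 1, seed = 1) {
  stopifnot(mitigation >= 0, mitigation <= 1, end_year > max(fit$years))
  future_years <- (max(fit$years) + 1):end_year
  params <- fit$params_hat
  hist_cov <- fit$forcings$covariates
  centers <- attr(hist_cov, "centers")
  scales <- attr(hist_cov, "scales")
  ov <- fit$forcings$overlap
  recent <- sort(unique(ov$year), decreasing = TRUE)[1:min(5, length(unique(ov$year)))]
  fut_ov <- ov %>%
    filter(.data$year %in% recent) %>%
    group_by(.data$fleet, .data$stage) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    mutate(scale = ifelse(all_fleets | .data$fleet == "trawl", 1 - mitigation, 1),
           value = .data$value * .data$scale) %>%
    select(-"scale") %>%
    crossing(year = future_years)
  hist_raw <- hist_cov[, c("year", "rainfall", "threshold_days", "ssha")]
  draws <- map_dfr(seq_len(n_draws), function(j) {
    raw <- if (is.null(scenario)) {
      build_scenario(hist_raw, future_years, "climate_neutral",
                     ssha_multiplier = ssha_multiplier, seed = seed + j)
    } else {
      sc <- scenario[match(future_years, scenario$year), ]
      if (anyNA(sc$year)) abort("scenario does not cover the projection years")
      if (!is.null(ssha_multiplier)) {
        sc$ssha <- (1 + ssha_multiplier) * mean(hist_raw$ssha, na.rm = TRUE)
      }
      sc
    }
    cov <- build_covariates(raw = raw, centers = centers, scales = scales)
    run <- run_population(params, list(covariates = cov, overlap = fut_ov),
                          future_years, init_state = fit$run$state)
    tibble(draw = j, year = run$records$year, pairs = run$records$pairs,
           breeding_success = run$records$breeding_success)
  })
  structure(list(draws = draws, end_year = end_year, mitigation = mitigation,
                 all_fleets = all_fleets, ssha_multiplier = ssha_multiplier,
                 scenario_source = if (is.null(scenario)) "climate_neutral" else "climate_model",
                 n_draws = n_draws, seed = seed),
            class = "alb_projection")
}

#' @method glance alb_projection
#' @export
glance.alb_projection <- function(x, ...) {
  pf <- x$draws[x$draws$year == x$end_year, ]
  tibble(
    scenario = x$scenario_source, mitigation = x$mitigation,
    ssha_multiplier = x$ssha_multiplier %||% NA_real_,
    n_draws = x$n_draws,
    median_pairs = median(pf$pairs),
    q25_pairs = quantile(pf$pairs, 0.25, names = FALSE),
    q75_pairs = quantile(pf$pairs, 0.75, names = FALSE)
  )
}

#' @method tidy alb_projection
#' @export
tidy.alb_projection <- function(x, ...) {
  x$draws[x$draws$year == x$end_year, c("draw", "pairs", "breeding_success")]
}

#' Factorial scenario-by-option projection grid
#'
#' Runs every combination of scenario, mitigation level and SSHA multiplier
#' and summarises the projected breeding pairs at the final year, with each
#' combination's ratio to the climate-neutral, zero-mitigation median.
#'
#' @param fit An `alb_fit`.
#' @param scenarios Named list of scenario tibbles; a `NULL` element means
#'   climate-neutral. Must include one named `"climate_neutral"` (the
#'   reference).
#' @param mitigations Numeric vector of mitigation fractions.
#' @param ssha_multipliers Vector of SSHA multipliers (`NA` = none).
#' @param end_year,n_draws,seed As in [project_population()].
#' @param ... Passed to [project_population()].
#' @return List with `draws` (per-combination final-year pairs per draw)
#'   and `summary` (medians, quartiles and `ratio_to_neutral`).
#' @export
scenario_grid <- function(fit, scenarios = list(climate_neutral = NULL),
                          mitigations = 0, ssha_multipliers = NA,
                          end_year = 2100, n_draws = 1, seed = 1, ...) {
  if (!"climate_neutral" %in% names(scenarios)) {
    scenarios <- c(list(climate_neutral = NULL), scenarios)
  }
  combos <- expand_grid(scenario = names(scenarios), mitigation = mitigations,
                        ssha_multiplier = ssha_multipliers)
  draws <- pmap(combos, function(scenario, mitigation, ssha_multiplier) {
    pr <- project_population(
      fit, scenario = scenarios[[scenario]], mitigation = mitigation,
      ssha_multiplier = if (is.na(ssha_multiplier)) NULL else ssha_multiplier,
      end_year = end_year, n_draws = n_draws, seed = seed, ...
    )
    mutate(tidy(pr), scenario = scenario, mitigation = mitigation,
           ssha_multiplier = ssha_multiplier)
  })
  draws <- bind_rows(draws)
  summ <- draws %>%
    group_by(.data$scenario, .data$mitigation, .data$ssha_multiplier) %>%
    summarise(median_pairs = median(.data$pairs),
              q25 = quantile(.data$pairs, 0.25, names = FALSE),
              q75 = quantile(.data$pairs, 0.75, names = FALSE),
              .groups = "drop")
  neutral <- summ$median_pairs[summ$scenario == "climate_neutral" &
                                 summ$mitigation == min(mitigations) &
                                 (is.na(summ$ssha_multiplier) |
                                    summ$ssha_multiplier == ssha_multipliers[1])][1]
  summ$ratio_to_neutral <- summ$median_pairs / neutral
  list(draws = draws, summary = summ)
}

#' Smallest mitigation level offsetting a climate scenario
#'
#' Scans a mitigation grid for the smallest level at which the scenario's
#' median final-year breeding pairs reach at least the climate-neutral
#' zero-mitigation median. Returns `NA` (flagged via the `attained`
#' attribute) when even full mitigation does not offset the scenario.
#'
#' @param fit An `alb_fit`.
#' @param scenario Scenario tibble (or `NULL` for climate-neutral, in which
#'   case the threshold is 0 by construction).
#' @param mitigations Ordered grid of mitigation fractions to scan.
#' @param end_year,n_draws,seed As in [project_population()].
#' @param ... Passed to [project_population()].
#' @return The threshold mitigation fraction (or `NA`), with attributes
#'   `attained` and `medians` (the scanned tibble).
#' @export
mitigation_threshold <- function(fit, scenario = NULL,
                                 mitigations = seq(0, 1, by = 0.1),
                                 end_year = 2100, n_draws = 1, seed = 1, ...) {
  mitigations <- sort(mitigations)
  neutral <- glance(project_population(fit, NULL, mitigation = 0,
                                       end_year = end_year, n_draws = n_draws,
                                       seed = seed, ...))$median_pairs
  meds <- map_dfr(mitigations, function(m) {
    g <- glance(project_population(fit, scenario, mitigation = m,
                                   end_year = end_year, n_draws = n_draws,
                                   seed = seed, ...))
    tibble(mitigation = m, median_pairs = g$median_pairs)
  })
  ok <- meds$mitigation[meds$median_pairs >= neutral]
  out <- if (length(ok)) min(ok) else NA_real_
  attr(out, "attained") <- length(ok) > 0
  attr(out, "medians") <- mutate(meds, neutral_median = neutral)
  out
}

#' @method autoplot alb_projection
#' @export
autoplot.alb_projection <- function(object, ...) {
  pf <- object$draws[object$draws$year == object$end_year, ]
  ggplot(object$draws, aes(x = .data$year, y = .data$pairs, group = .data$draw)) +
    geom_line(alpha = 0.4) +
    geom_hline(yintercept = median(pf$pairs), linetype = 2) +
    labs(x = "Year", y = "Breeding pairs",
         title = sprintf("Projection to %d (%s, %.0f%% mitigation)",
                         object$end_year, object$scenario_source,
                         100 * object$mitigation)) +
    theme_minimal()
}

#' @method autoplot alb_fit
#' @export
autoplot.alb_fit <- function(object, ...) {
  rec <- object$run$records
  obs <- object$obs
  long_rec <- rec %>%
    select("year", "pairs", "breeding_success") %>%
    pivot_longer(-"year", names_to = "type", values_to = "expected")
  obs2 <- obs %>%
    filter(.data$type %in% c("pairs", "breeding_success")) %>%
    select("type", "year", "value", "excluded")
  ggplot(long_rec, aes(x = .data$year, y = .data$expected)) +
    geom_line() +
    geom_point(data = obs2, aes(y = .data$value, shape = .data$excluded)) +
    scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1), guide = "none") +
    facet_wrap(~type, scales = "free_y", ncol = 1) +
    labs(x = "Year", y = NULL,
         title = sprintf("Observed vs expected (%s, b = %g)", object$subset, object$b)) +
    theme_minimal()
}
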