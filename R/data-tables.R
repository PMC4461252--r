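#' Long-term monitoring observations for Albatross Island
#'
#' Annual monitoring series for the Albatross Island shy albatross colony:
#' estimated breeding pairs, chicks fledged, breeding success (fledged /
#' pairs), first-year juvenile survival by cohort, and adult return rates
#' (probability of breeding given an attempt the previous season). Years are
#' model years: year `y` denotes the breeding season that starts 1 October of
#' calendar year `y`. Missing entries are seasons in which that quantity was
#' not recorded.
#'
#' @return A tibble with columns `year`, `pairs`, `fledged`,
#'   `breeding_success`, `juvenile_survival`, `return_rate`.
#' @export
albatross_observations <- function() {
  path <- system.file("extdata", "monitoring_observations.csv", package = "albipm")
  as_tibble(read.csv(path))
}

#' Maturity ogive: cumulative probability of first breeding by age
#'
#' @return A tibble with columns `age` and `p_first_breeding` (cumulative
#'   probability, reaching 1 at age 16).
#' @export
maturity_ogive <- function() {
  path <- system.file("extdata", "maturity_ogive.csv", package = "albipm")
  out <- as_tibble(read.csv(path))
  out$p_first_breeding <- out$first_breeding_pct / 100
  out[, c("age", "p_first_breeding")]
}

#' Reported fishery effort totals within the foraging range
#'
#' Total effort of each contributing fishery inside the bird foraging area,
#' grouped into the three super-fleets (trawl in operations, pelagic and
#' demersal longline in millions of hooks).
#'
#' @return A tibble with columns `super_fleet`, `fishery`, `effort`, `unit`.
#' @export
fleet_effort_totals <- function() {
  path <- system.file("extdata", "fleet_effort_totals.csv", package = "albipm")
  as_tibble(read.csv(path))
}

#' The single observed trawl bycatch-rate datum
#'
#' A fleet-wide observer program recorded 31 'shy-type' albatross captures in
#' 856 trawl operations (2006, Commonwealth Trawl Sector). Mid-2000s colony
#' censuses put Albatross Island at 5200 birds of a 14870-bird species total
#' (Mewstone 9500, Pedra Branca 170), so the Albatross Island population is
#' apportioned its colony share of the observed rate.
#'
#' @param birds_caught,trawls_observed Observed captures and observed effort.
#' @param colony_sizes Named numeric vector of colony sizes (birds).
#' @param colony Colony whose share is wanted.
#' @return A one-row tibble: observed rate per 1000 trawls
#'   (`observed_rate_per_1000`), the colony share (`colony_share`), and the
#'   apportioned per-population rate (`population_rate_per_1000`).
#' @export
bycatch_observation <- function(birds_caught = 31, trawls_observed = 856,
                                colony_sizes = c(albatross_island = 5200,
                                                 mewstone = 9500,
                                                 pedra_branca = 170),
                                colony = "albatross_island") {
  stopifnot(trawls_observed > 0, colony %in% names(colony_sizes))
  observed_rate <- 1000 * birds_caught / trawls_observed
  share <- unname(colony_sizes[colony] / sum(colony_sizes))
  tibble(
    observed_rate_per_1000 = observed_rate,
    colony_share = share,
    population_rate_per_1000 = share * observed_rate
  )
}
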