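#' Parameter set for the albatross population model
#'
#' Bundles every estimated or fixed quantity of the population model. The
#' model year runs 1 October to 30 September; chicks are reared October
#' through May (8 months) and fledge at the end of May.
#'
#' Density dependence acts on chick survival: extrinsic chick survival
#' interpolates between a compensated maximum `s_max` at low density and the
#' pristine anchor at carrying capacity,
#' `s(N) = s_K + (s_max - s_K) (1 - (N/K)^z_c)`, where `s_K` is tied to the
#' pristine breeding success `bs0` and within-season parent survival so that
#' breeding success equals `bs0` exactly at `N = K` under mean environment
#' and no fishing.
#'
#' First-year juvenile natural mortality `Mj` closes the life cycle: when
#' `NULL` (default) it is solved internally so the annual life-cycle map has
#' dominant eigenvalue 1 at carrying capacity, making K a true equilibrium
#' of the unfished model. Supplying `Mj` overrides this (K-equilibrium then
#' not guaranteed).
#'
#' @param M Instantaneous adult natural mortality per year.
#' @param bs0 Breeding success of the pristine population at K.
#' @param s_max Ceiling on extrinsic chick survival as density falls to 0.
#' @param z_c Density-dependence shape exponent on chick survival.
#' @param q Named catchability vector per super-fleet (per overlap-index
#'   unit per year).
#' @param effect An [env_effect()] linking standardized covariates to chick
#'   mortality.
#' @param h_pre Pre-model harvest depletion: initial breeding pairs as a
#'   fraction of K.
#' @param K Carrying capacity in breeding pairs.
#' @param Mj First-year juvenile instantaneous natural mortality, or `NULL`
#'   to solve for equilibrium at K.
#' @param ogive Maturity ogive tibble (`age`, `p_first_breeding`); must
#'   reach 1 by age 16.
#' @param return_rate Default breeding frequency outside observed years.
#' @return An object of class `alb_params`.
#' @export
albatross_params <- function(M = 0.041, bs0 = 0.42, s_max = 0.70, z_c = 1,
                             q = c(trawl = 0, pelagic_longline = 0, demersal_longline = 0),
                             effect = env_effect(), h_pre = 0.1, K = 12000,
                             Mj = NULL, ogive = maturity_ogive(),
                             return_rate = 0.95) {
  stopifnot(M >= 0, bs0 > 0, bs0 < 1, z_c > 0, all(q >= 0),
            h_pre > 0, h_pre <= 1, K > 0,
            return_rate > 0, return_rate <= 1)
  if (abs(ogive$p_first_breeding[nrow(ogive)] - 1) > 1e-12) {
    abort("maturity ogive must reach 1 at its final age")
  }
  p <- structure(
    list(M = M, bs0 = bs0, s_max = s_max, z_c = z_c, q = q, effect = effect,
         h_pre = h_pre, K = K, Mj = Mj, ogive = ogive,
         return_rate = return_rate, chick_months = 8),
    class = "alb_params"
  )
  if (s_K(p) >= s_max) {
    abort("s_max must exceed the chick survival anchored at K (raise s_max or lower bs0)")
  }
  p
}

# extrinsic chick survival at carrying capacity, anchored so that breeding
# success at K (mean environment, no fishing) equals bs0:
# bs0 = s_K * exp(-2 M * 8/12)   (both parents survive the 8 chick months)
s_K <- function(params) {
  params$bs0 / exp(-2 * params$M * params$chick_months / 12)
}

# conditional recruitment probabilities by age from the cumulative ogive
ogive_rho <- function(ogive) {
  g <- c(0, ogive$p_first_breeding)
  rho <- (g[-1] - g[-length(g)]) / (1 - g[-length(g)])
  rho[!is.finite(rho)] <- 1
  setNames(rho, ogive$age)
}

#' Density-dependent, environment-forced chick mortality
#'
#' Returns the instantaneous annual chick mortality rate
#' `My0 = -log(s(N_b)) x env_mult`, where `s(N_b)` is the density-dependent
#' extrinsic chick survival and `env_mult` the combined environmental
#' multiplier ([env_multiplier()]; 1 at mean conditions). The dynamics
#' spread the rate uniformly over the 8 chick-rearing months. `N_b > K` is
#' allowed (soft ceiling: survival falls below the K anchor).
#'
#' @param params An [albatross_params()].
#' @param n_pairs Breeding pairs this season.
#' @param env_mult Combined environmental multiplier.
#' @return Instantaneous annual chick mortality rate (positive scalar).
#' @export
chick_mortality <- function(params, n_pairs, env_mult = 1) {
  if (n_pairs > params$K) {
    warn("breeding pairs exceed carrying capacity; density-dependent survival below the K anchor",
         .frequency = "once", .frequency_id = "albipm_nb_gt_k")
  }
  sK <- s_K(params)
  s <- sK + (params$s_max - sK) * (1 - (n_pairs / params$K)^params$z_c)
  s <- min(max(s, 1e-8), 1 - 1e-8)
  -log(s) * env_mult
}

# --- annual life-cycle map (one sex, females; zero fishing) -----------------
# Compartments at 1 October, just after ageing/recruitment/pair formation:
# J1..J4, PB5..PB15 (pre-breeders by age; all recruit by 16), NB, B (= pairs).
# Used to (i) solve Mj for equilibrium at K and (ii) get the stable structure.
annual_matrix <- function(params, s_chick, Mj = params$Mj) {
  M <- params$M
  r <- params$return_rate
  rho <- ogive_rho(params$ogive)
  sa <- exp(-M)
  sj1 <- exp(-Mj)
  nm <- c(paste0("J", 1:4), paste0("PB", 5:15), "NB", "B")
  n <- length(nm)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  # reproduction: B pairs -> fledglings (extrinsic chick survival, both-parent
  # survival over the 8 chick months, 50:50 sex split, 4 months at Mj to 1 Oct)
  A["J1", "B"] <- s_chick * exp(-2 * M * params$chick_months / 12) * 0.5 * exp(-Mj * 4 / 12)
  A["J2", "J1"] <- sj1
  A["J3", "J2"] <- sa
  A["J4", "J3"] <- sa
  # J4 survive, turn 5, recruit with rho[5]
  A["B", "J4"] <- sa * rho[["5"]]
  A["PB5", "J4"] <- sa * (1 - rho[["5"]])
  for (a in 5:15) {
    from <- paste0("PB", a)
    A["B", from] <- sa * rho[[as.character(a + 1)]]
    if (a < 15) A[paste0("PB", a + 1), from] <- sa * (1 - rho[[as.character(a + 1)]])
  }
  A["B", "NB"] <- sa        # skippers return
  A["B", "B"] <- A["B", "B"] + sa * r
  A["NB", "B"] <- sa * (1 - r)
  A
}

lifecycle_lambda <- function(params, s_chick, Mj) {
  ev <- eigen(annual_matrix(params, s_chick, Mj), only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

# Solve first-year juvenile mortality for equilibrium at carrying capacity.
# At replacement (lambda = 1) the renewal condition of the life-cycle map is
# closed-form: per breeding female, fledged female production is
# phi = s_K exp(-2M*8/12) * 0.5 * exp(-Mj/3), survival from age-1 juvenile to
# recruitment at age a is exp(-Mj) sa^(a-2) dg_a (dg = ogive increments), and
# the breeder pool self-renews at rate sa*r + sa^2*(1-r) (returners plus
# one-season skippers). Setting total renewal to 1 and solving for Mj:
solve_Mj <- function(params) {
  M <- params$M
  sa <- exp(-M)
  r <- params$return_rate
  g <- params$ogive$p_first_breeding
  dg <- diff(c(0, g))
  ages <- params$ogive$age
  rec_sum <- sum(sa^(ages - 2) * dg)
  phi0 <- s_K(params) * exp(-2 * M * params$chick_months / 12) * 0.5
  need <- 1 - sa * r - sa^2 * (1 - r)
  if (need <= 0) abort("no equilibrium at K: adult pool renews itself without reproduction")
  # need = phi0 * exp(-Mj/3) * exp(-Mj) * rec_sum  =>  exp(-4Mj/3) = need/(phi0*rec_sum)
  ratio <- need / (phi0 * rec_sum)
  if (ratio >= 1) {
    abort("no equilibrium at K: life cycle cannot replace itself even with zero juvenile mortality")
  }
  -0.75 * log(ratio)
}

#' Initialize the population state
#'
#' Builds the state at 1 October of the first model year: the stable
#' age/stage structure of the unfished life cycle at the initial density
#' (the leading eigenvector of the annual life-cycle map, evaluated at the
#' depleted chick survival), with a 50:50 sex ratio, scaled so the first
#' season's breeding pairs equal `h_pre x K` (pre-model harvest depletion).
#' Pairs are already formed and eggs laid; [run_population()] detects this
#' and starts the first year directly.
#'
#' @param params An [albatross_params()].
#' @param start_year First model year (default 1942).
#' @return An `alb_state` list; pass to [run_population()].
#' @export
init_population <- function(params, start_year = 1942) {
  if (is.null(params$Mj)) params$Mj <- solve_Mj(params)
  n0 <- params$h_pre * params$K
  sK0 <- s_K(params)
  s_c <- sK0 + (params$s_max - sK0) * (1 - params$h_pre^params$z_c)
  A <- annual_matrix(params, s_c)
  eg <- eigen(A)
  v <- abs(Re(eg$vectors[, which.max(Re(eg$values))]))
  names(v) <- rownames(A)
  v <- v * n0 / v[["B"]]   # breeding pairs = h_pre x K
  state <- list(
    year = start_year, month = 1L,
    J = rbind(female = v[paste0("J", 1:4)], male = v[paste0("J", 1:4)]),
    PB = rbind(female = v[paste0("PB", 5:15)], male = v[paste0("PB", 5:15)]),
    B = c(female = v[["B"]], male = v[["B"]]),
    NB = c(female = v[["NB"]], male = v[["NB"]]),
    P = n0, C = n0, FL = c(female = 0, male = 0),
    params_Mj = params$Mj, at_season_start = TRUE,
    kills = NULL, deaths_last = NA_real_
  )
  class(state) <- "alb_state"
  state
}

state_total <- function(state) {
  sum(state$J) + sum(state$PB) + sum(state$B) + sum(state$NB) +
    state$C + sum(state$FL)
}

#' Ageing, recruitment and pair formation at the season start (1 October)
#'
#' Advances the state into a new model year: fledged birds become age-1
#' juveniles, juveniles and pre-breeders age one class, pre-breeders recruit
#' according to the maturity ogive, previous-season breeders re-attempt with
#' probability `return_rate`, last season's non-breeders rejoin, pairs form
#' as the minimum of male and female candidates (excess singles sit out the
#' season as non-breeders), and each pair lays one egg.
#'
#' @param state An `alb_state`.
#' @param params An [albatross_params()].
#' @param return_rate Breeding frequency for this season.
#' @return Updated state at month 1 (October) of the next model year.
#' @export
recruit_and_breed <- function(state, params, return_rate = params$return_rate,
                              rho = ogive_rho(params$ogive)) {
  J <- state$J; PB <- state$PB
  newJ <- J
  newJ[, 2:4] <- J[, 1:3]
  newJ[, 1] <- state$FL
  age5 <- J[, 4]
  rho5 <- rho[[1]]
  recruits <- age5 * rho5 + as.vector(PB %*% rho[2:12])
  newPB <- PB
  newPB[, 2:11] <- PB[, 1:10] * rep(1 - rho[2:11], each = 2)
  newPB[, 1] <- age5 * (1 - rho5)
  cand <- recruits + state$B * return_rate + state$NB
  P <- min(cand)
  state$J <- newJ
  state$PB <- newPB
  state$NB <- state$B * (1 - return_rate) + (cand - P)
  state$B <- c(female = P, male = P)
  state$P <- P
  state$C <- P       # one egg per pair
  state$FL <- c(female = 0, male = 0)
  state$year <- state$year + 1
  state$month <- 1L
  state
}

# annual forcing for one model year: total and per-fleet fishing mortality by
# stage grid, plus the environment-adjusted chick mortality rate
year_forcing <- function(params, x_cov, F_adult, F_juv, n_pairs) {
  mult <- env_multiplier(params$effect, x_cov)
  list(
    F_adult = F_adult, F_juv = F_juv,
    My0 = chick_mortality(params, n_pairs, mult),
    env_mult = mult
  )
}

#' One monthly time step of the population dynamics
#'
#' Applies competing instantaneous rates within the month (natural mortality
#' and per-fleet fishing mortality, each one-twelfth of the annual rate)
#' through a joint exponential survival, with chick survival additionally
#' multiplied by both parents' within-month survival ("the death of either
#' parent leads to breeding failure"). Chicks fledge after the month-8 step
#' (end of May). The calendar advances one month; ageing and breeding happen
#' at 1 October via [recruit_and_breed()].
#'
#' @param state An `alb_state` at some month 1..12 (month 1 = October).
#' @param params An [albatross_params()] (with `Mj` resolved).
#' @param forcing List with named per-fleet annual rates `F_adult`, `F_juv`
#'   and the annual chick mortality `My0` (environment-adjusted).
#' @return Updated state; `state$deaths_last` holds total deaths this month
#'   and `state$kills` accumulates per-fleet kills.
#' @export
monthly_step <- function(state, params, forcing) {
  Mj <- state$params_Mj %||% params$Mj
  m <- state$month
  Fa <- sum(forcing$F_adult); Fj <- sum(forcing$F_juv)
  za <- (params$M + Fa) / 12
  zj1 <- (Mj + Fj) / 12
  zj <- (params$M + Fj) / 12
  sa <- exp(-za); sj1 <- exp(-zj1); sj <- exp(-zj)
  before <- state_total(state)
  if (is.null(state$kills)) {
    state$kills <- tibble(fleet = character(), year = integer(),
                          stage = character(), kills = numeric())
  }
  add_kills <- function(kills, N0, z_ann, F_f, stage) {
    if (all(F_f == 0) || N0 <= 0) return(kills)
    deaths <- N0 * (1 - exp(-z_ann / 12))
    bind_rows(kills, tibble(
      fleet = names(F_f), year = state$year, stage = stage,
      kills = unname(deaths * F_f / z_ann)
    ))
  }
  n_ad <- sum(state$B) + sum(state$NB) + sum(state$PB)
  state$kills <- add_kills(state$kills, n_ad, params$M + Fa, forcing$F_adult, "adult")
  state$kills <- add_kills(state$kills, sum(state$J[, 1]) + sum(state$FL),
                           Mj + Fj, forcing$F_juv, "juvenile")
  state$kills <- add_kills(state$kills, sum(state$J[, 2:4]),
                           params$M + Fj, forcing$F_juv, "juvenile")
  state$B <- state$B * sa
  state$NB <- state$NB * sa
  state$PB <- state$PB * sa
  state$J[, 1] <- state$J[, 1] * sj1
  state$J[, 2:4] <- state$J[, 2:4] * sj
  state$FL <- state$FL * sj1
  if (m <= params$chick_months) {
    sc <- exp(-forcing$My0 / params$chick_months)
    state$C <- state$C * sc * sa * sa   # extrinsic x both parents survive
    state$P <- state$P * sa * sa
  }
  if (m == params$chick_months) {
    state$FL <- state$FL + c(female = state$C / 2, male = state$C / 2)
    state$C <- 0
  }
  state$deaths_last <- before - state_total(state)
  state$month <- m + 1L
  state
}

# closed-form advance of 12 months at constant within-year rates; agrees with
# 12 monthly_step() calls to machine precision and is what run_population()
# uses. Returns per-fleet kill vectors instead of growing a table.
year_step_fast <- function(state, params, forcing) {
  Mj <- state$params_Mj
  cm <- params$chick_months
  Fa <- sum(forcing$F_adult); Fj <- sum(forcing$F_juv)
  za <- params$M + Fa; zj1 <- Mj + Fj; zj <- params$M + Fj
  sa <- exp(-za)
  P0 <- state$P
  # chick survival to fledging: extrinsic + both parents over the chick months
  C_fl <- state$C * exp(-forcing$My0) * exp(-2 * za * cm / 12)
  fl_end <- C_fl * exp(-zj1 * (12 - cm) / 12)
  k_ad <- k_juv <- setNames(rep(0, length(forcing$F_adult)), names(forcing$F_adult))
  n_ad <- sum(state$B) + sum(state$NB) + sum(state$PB)
  if (Fa > 0 && n_ad > 0) k_ad <- n_ad * (1 - sa) * forcing$F_adult / za
  if (Fj > 0) {
    d1 <- sum(state$J[, 1]) * (1 - exp(-zj1)) + C_fl * (1 - exp(-zj1 * (12 - cm) / 12))
    d2 <- sum(state$J[, 2:4]) * (1 - exp(-zj))
    k_juv <- d1 * forcing$F_juv / zj1 + d2 * forcing$F_juv / zj
  }
  state$B <- state$B * sa
  state$NB <- state$NB * sa
  state$PB <- state$PB * sa
  state$J[, 1] <- state$J[, 1] * exp(-zj1)
  state$J[, 2:4] <- state$J[, 2:4] * exp(-zj)
  state$FL <- c(female = fl_end / 2, male = fl_end / 2)
  state$C <- 0
  state$P <- P0 * exp(-2 * za * cm / 12)
  state$month <- 13L
  list(state = state, fledged = C_fl, adult_survival = sa,
       Fa = Fa, Fj = Fj, k_ad = k_ad, k_juv = k_juv)
}

#' Run the population model over a span of model years
#'
#' Full deterministic trajectory: initialization (unless `init_state` is
#' given), then for each model year pair formation, environment- and
#' density-forced chick mortality, fishing mortality from the overlap
#' indices, and survival bookkeeping. Emits the expected observation series
#' the likelihood conditions on.
#'
#' @param params An [albatross_params()].
#' @param forcings List with elements `covariates` (tibble from
#'   [build_covariates()]; years absent default to mean conditions x = 0),
#'   `overlap` (tibble `fleet`, `year`, `stage`, `value`; absent years mean
#'   no fishing) and optionally `return_rates` (tibble `year`, `value`).
#' @param years Model years to simulate.
#' @param init_state Optional starting `alb_state` (e.g. to continue a
#'   fitted trajectory into the future).
#' @param monthly If `TRUE`, advance with 12 explicit [monthly_step()] calls
#'   instead of the equivalent closed form (slower; for verification).
#' @return An `alb_run`: list with `records` (tibble year, pairs, fledged,
#'   breeding_success, adult_survival, env_mult, My0, F_adult, F_juv,
#'   return_rate), `kills` (tibble fleet, year, stage, kills), `state`
#'   (final), `params` (with solved `Mj`).
#' @export
run_population <- function(params, forcings = list(), years,
                           init_state = NULL, monthly = FALSE) {
  state <- if (is.null(init_state)) init_population(params, start_year = years[1]) else init_state
  params$Mj <- state$params_Mj
  cov <- forcings$covariates
  ov <- forcings$overlap
  rr <- forcings$return_rates
  qv <- params$q
  fleets <- names(qv)
  ny <- length(years)
  nf <- length(fleets)
  K_ad <- K_juv <- matrix(0, ny, nf, dimnames = list(NULL, fleets))
  rec_pairs <- rec_fl <- rec_sa <- rec_env <- rec_my0 <- rec_fa <- rec_fj <- rec_rr <- numeric(ny)
  # vectorized forcing lookup: year x fleet fishing-mortality matrices and a
  # year x covariate matrix, built once per run
  FA <- FJ <- matrix(0, ny, nf, dimnames = list(NULL, fleets))
  if (!is.null(ov)) {
    ri <- match(ov$year, years)
    ci <- match(ov$fleet, fleets)
    keep <- !is.na(ri) & !is.na(ci)
    ia <- keep & ov$stage == "adult"
    ij <- keep & ov$stage == "juvenile"
    FA[cbind(ri[ia], ci[ia])] <- qv[ci[ia]] * ov$value[ia]
    FJ[cbind(ri[ij], ci[ij])] <- qv[ci[ij]] * ov$value[ij]
  }
  X <- matrix(0, ny, 3, dimnames = list(NULL, c("rainfall", "threshold_days", "ssha")))
  if (!is.null(cov)) {
    ri <- match(years, cov$year)
    ok <- !is.na(ri)
    X[ok, ] <- cbind(cov$x_rainfall[ri[ok]], cov$x_threshold_days[ri[ok]],
                     cov$x_ssha[ri[ok]])
    X[is.na(X)] <- 0
  }
  RR <- rep(params$return_rate, ny)
  if (!is.null(rr)) {
    ri <- match(years, rr$year)
    ok <- !is.na(ri) & !is.na(rr$value[ri])
    RR[ok] <- rr$value[ri[ok]]
  }
  rho <- ogive_rho(params$ogive)
  # hoisted constants for the inlined chick-mortality/environment arithmetic
  # (must mirror chick_mortality() and env_multiplier(); a test asserts this)
  sKv <- s_K(params)
  th3 <- c(rainfall = 0, threshold_days = 0, ssha = 0)
  th3[names(params$effect$theta)] <- params$effect$theta
  b_pow <- params$effect$b
  if (monthly) {
    for (i in seq_len(ny)) {
      y <- years[i]
      r_y <- RR[i]
      if (isTRUE(state$at_season_start)) {
        state$at_season_start <- FALSE
        state$year <- y
      } else {
        state <- recruit_and_breed(state, params, return_rate = r_y, rho = rho)
      }
      xi <- X[i, ]
      mult <- exp(sum(th3 * sign(xi) * abs(xi)^b_pow))
      s_dd <- sKv + (params$s_max - sKv) * (1 - (state$P / params$K)^params$z_c)
      s_dd <- min(max(s_dd, 1e-8), 1 - 1e-8)
      frc <- list(F_adult = FA[i, ], F_juv = FJ[i, ],
                  My0 = -log(s_dd) * mult, env_mult = mult)
      pairs0 <- state$P
      for (m in 1:12) state <- monthly_step(state, params, frc)
      Fj_t <- sum(FJ[i, ]); Fa_t <- sum(FA[i, ])
      fl <- sum(state$FL) / exp(-(params$Mj + Fj_t) * (12 - params$chick_months) / 12)
      rec_pairs[i] <- pairs0; rec_fl[i] <- fl
      rec_sa[i] <- exp(-(params$M + Fa_t))
      rec_env[i] <- mult; rec_my0[i] <- frc$My0
      rec_fa[i] <- Fa_t; rec_fj[i] <- Fj_t; rec_rr[i] <- r_y
    }
  } else {
    # inlined equivalent of recruit_and_breed() + year_step_fast() on local
    # variables (verified against the monthly route by tests)
    M <- params$M; cm <- params$chick_months
    Mj <- params$Mj; z_c <- params$z_c; s_max <- params$s_max; Kcap <- params$K
    J <- state$J; PB <- state$PB; B2 <- state$B; NB <- state$NB
    P <- state$P; C <- state$C; FL <- state$FL
    at_start <- isTRUE(state$at_season_start)
    rho5 <- rho[[1]]; rho_rest <- rho[2:12]
    om_rho <- rep(1 - rho[2:11], each = 2)
    cm_frac <- cm / 12; fl_frac <- (12 - cm) / 12
    for (i in seq_len(ny)) {
      r_y <- RR[i]
      if (at_start) {
        at_start <- FALSE
      } else {
        age5 <- J[, 4]
        recruits <- age5 * rho5 + as.vector(PB %*% rho_rest)
        J[, 2:4] <- J[, 1:3]
        J[, 1] <- FL
        PB[, 2:11] <- PB[, 1:10] * om_rho
        PB[, 1] <- age5 * (1 - rho5)
        cand <- recruits + B2 * r_y + NB
        P <- min(cand)
        NB <- B2 * (1 - r_y) + (cand - P)
        B2 <- c(P, P)
        C <- P
      }
      xi <- X[i, ]
      mult <- exp(sum(th3 * sign(xi) * abs(xi)^b_pow))
      s_dd <- sKv + (s_max - sKv) * (1 - (P / Kcap)^z_c)
      s_dd <- min(max(s_dd, 1e-8), 1 - 1e-8)
      My0 <- -log(s_dd) * mult
      Fa_f <- FA[i, ]; Fj_f <- FJ[i, ]
      Fa <- sum(Fa_f); Fj <- sum(Fj_f)
      za <- M + Fa; zj1 <- Mj + Fj; zj <- M + Fj
      sa <- exp(-za); sj1y <- exp(-zj1); sjy <- exp(-zj)
      C_fl <- C * exp(-My0) * exp(-2 * za * cm_frac)
      fl_end <- C_fl * exp(-zj1 * fl_frac)
      n_ad <- sum(B2) + sum(NB) + sum(PB)
      if (Fa > 0 && n_ad > 0) K_ad[i, ] <- n_ad * (1 - sa) * Fa_f / za
      if (Fj > 0) {
        d1 <- sum(J[, 1]) * (1 - sj1y) + C_fl * (1 - exp(-zj1 * fl_frac))
        d2 <- sum(J[, 2:4]) * (1 - sjy)
        K_juv[i, ] <- d1 * Fj_f / zj1 + d2 * Fj_f / zj
      }
      B2 <- B2 * sa
      NB <- NB * sa
      PB <- PB * sa
      J[, 1] <- J[, 1] * sj1y
      J[, 2:4] <- J[, 2:4] * sjy
      FL <- c(fl_end, fl_end) / 2
      rec_pairs[i] <- C; rec_fl[i] <- C_fl
      rec_sa[i] <- sa
      rec_env[i] <- mult; rec_my0[i] <- My0
      rec_fa[i] <- Fa; rec_fj[i] <- Fj; rec_rr[i] <- r_y
      C <- 0
      P <- rec_pairs[i] * exp(-2 * za * cm_frac)
    }
    state$J <- J; state$PB <- PB; state$B <- B2; state$NB <- NB
    state$P <- P; state$C <- 0; state$FL <- FL
    state$year <- years[ny]; state$month <- 13L
    state$at_season_start <- FALSE
  }
  records <- tibble::new_tibble(list(
    year = years, pairs = rec_pairs, fledged = rec_fl,
    breeding_success = rec_fl / rec_pairs, adult_survival = rec_sa,
    env_mult = rec_env, My0 = rec_my0, F_adult = rec_fa, F_juv = rec_fj,
    return_rate = rec_rr
  ), nrow = ny)
  if (monthly) {
    kills <- (state$kills %||%
                tibble(fleet = character(), year = integer(),
                       stage = character(), kills = numeric())) %>%
      group_by(.data$fleet, .data$year, .data$stage) %>%
      summarise(kills = sum(.data$kills), .groups = "drop")
  } else {
    kv <- c(as.vector(K_ad), as.vector(K_juv))
    keep <- kv > 0
    kills <- tibble::new_tibble(list(
      fleet = rep(rep(fleets, each = ny), 2)[keep],
      year = rep(years, 2 * nf)[keep],
      stage = rep(c("adult", "juvenile"), each = ny * nf)[keep],
      kills = kv[keep]
    ), nrow = sum(keep))
  }
  structure(
    list(records = records, kills = kills, state = state, params = params),
    class = "alb_run"
  )
}

#' First-year and to-age-5 juvenile survival expected by a model run
#'
#' The first juvenile period spans fledging (end of May) through the end of
#' the cohort's first full juvenile year: 4 months in the fledging season
#' plus 12 months the following model year, at first-year natural mortality
#' `Mj` plus juvenile-grid fishing. Survival to age 5 appends three further
#' years at adult natural mortality (plus juvenile-grid fishing), mirroring
#' the conditioning rule that adjusts observed first-year survival with
#' three additional years of adult mortality. Fishing rates beyond the run
#' horizon reuse the final simulated year.
#'
#' @param run An `alb_run`.
#' @param cohort_years Cohort (fledging) model years.
#' @return Tibble `year`, `s_first`, `s_to5`.
#' @export
juvenile_survival_expected <- function(run, cohort_years = run$records$year) {
  rec <- run$records
  Mj <- run$params$Mj
  M <- run$params$M
  fj <- function(y) {
    i <- match(y, rec$year)
    i[is.na(i)] <- nrow(rec)
    rec$F_juv[i]
  }
  s1 <- exp(-(Mj + fj(cohort_years)) / 3 - (Mj + fj(cohort_years + 1)))
  extra <- exp(-(3 * M + fj(cohort_years + 2) + fj(cohort_years + 3) +
                   fj(cohort_years + 4)))
  tibble(year = cohort_years, s_first = s1, s_to5 = s1 * extra)
}

#' Apparent juvenile survival to age 5 under incomplete recruitment
#'
#' Mark-recapture cohorts are only seen again once they recruit; a cohort
#' fledged in year `y` and observed through final data year `T` can only
#' have recruited up to age `T - y`. The expected apparent survival is the
#' true survival to age 5 times the ogive value at that age: 0 for a
#' final-year cohort, the full survival to 5 once the ogive is complete
#' (age >= 16).
#'
#' @param run An `alb_run`.
#' @param cohort_years Cohort years.
#' @param final_year Final data year.
#' @return Tibble `year`, `apparent_s5`.
#' @export
apparent_juvenile_survival_to5 <- function(run, cohort_years, final_year) {
  og <- run$params$ogive
  a <- final_year - cohort_years
  gv <- ifelse(a < min(og$age), 0,
               ifelse(a >= max(og$age), 1, og$p_first_breeding[match(a, og$age)]))
  js <- juvenile_survival_expected(run, cohort_years)
  tibble(year = cohort_years, apparent_s5 = js$s_to5 * gv)
}

#' Expected bycatch rate per 1000 effort units in a region
#'
#' Model-predicted kills of this population by a fleet inside a region and
#' year, divided by the fleet's regional effort in thousands. Kills are
#' distributed over cells in proportion to effort times stage utilisation,
#' so the regional share is the region's fraction of the overlap index.
#'
#' @param run An `alb_run`.
#' @param effort Effort tibble (`fleet`, `year`, `cell_lon`, `cell_lat`,
#'   `effort`).
#' @param utils Named list of utilisation grids: `juvenile`, `adult`.
#' @param fleet Fleet name.
#' @param year Model year.
#' @param region Named vector `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @return Birds per 1000 effort units (scalar).
#' @export
expected_bycatch_rate <- function(run, effort, utils, fleet = "trawl", year,
                                  region = ALB_BYCATCH_REGION) {
  ef <- effort[effort$fleet == fleet & effort$year == year, ]
  if (nrow(ef) == 0 || sum(ef$effort) == 0) return(0)
  in_region <- ef$cell_lon >= region[["lon_min"]] & ef$cell_lon < region[["lon_max"]] &
    ef$cell_lat >= region[["lat_min"]] & ef$cell_lat < region[["lat_max"]]
  eff_region <- sum(ef$effort[in_region])
  if (eff_region == 0) return(0)
  kl <- run$kills[run$kills$fleet == fleet & run$kills$year == year, ]
  if (nrow(kl) == 0) return(0)
  frac <- function(stage) {
    u <- utils[[stage]]
    w <- setNames(u$weight, paste(u$cell_lon, u$cell_lat))
    wv <- w[paste(ef$cell_lon, ef$cell_lat)]
    wv[is.na(wv)] <- 0
    tot <- sum(ef$effort * wv)
    if (tot == 0) return(0)
    sum(ef$effort[in_region] * wv[in_region]) / tot
  }
  kills_region <- sum(vapply(seq_len(nrow(kl)), function(i) {
    kl$kills[i] * frac(kl$stage[i])
  }, numeric(1)))
  kills_region / (eff_region / 1000)
}

#' @export
print.alb_run <- function(x, ...) {
  rec <- x$records
  cat("<alb_run> ", min(rec$year), "-", max(rec$year), "\n", sep = "")
  cat("  final breeding pairs:", round(tail(rec$pairs, 1), 1), "\n")
  cat("  mean breeding success:", round(mean(rec$breeding_success), 3), "\n")
  if (nrow(x$kills) > 0) {
    tot <- x$kills %>% group_by(.data$fleet) %>% summarise(kills = sum(.data$kills))
    cat("  total bycatch:", paste(tot$fleet, round(tot$kills), collapse = ", "), "\n")
  }
  invisible(x)
}
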