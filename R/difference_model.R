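# Infinite-population, drift-free implementation of the life-history model.
# Flies are grouped into cohorts keyed by (preference bin, birth day,
# developmental site): every member of such a cohort experiences exactly
# the same temperature path, so real-valued cohort densities with shared
# development/senescence progress reproduce the agent model's expectation
# without discretizing progress.  The only discretization is the
# preference grid itself.

new_cohorts <- function(bin = integer(0), site = numeric(0),
                        density = numeric(0), dev = numeric(0),
                        sen = numeric(0), adult = logical(0)) {
  list(bin = bin, site = site, density = density, dev = dev, sen = sen,
       adult = adult)
}

#' Initialize the cohort table
#'
#' Total density equals `n_seed`; the preference marginal equals the grid
#' weights.  Under the default overwinter seeding, each bin's density is
#' spread uniformly over `n_age` age slices on `[M(T1), A(T1)]` (all
#' adults); under `init = "egg"` each bin is a single egg-stage cohort.
#'
#' @param params A [model_params].
#' @param grid A [pref_grid].
#' @param w A `weather_series`.
#' @param n_age Age slices per bin for the overwinter seeding.
#' @return A cohort table (list of parallel vectors `bin`, `site`,
#'   `density`, `dev`, `sen`, `adult`).
#' @export
init_density <- function(params, grid, w, n_age = 25L) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "pref_grid"),
            inherits(w, "weather_series"))
  T1 <- effective_temperature(w)[1L]
  M1 <- eclosion_time(T1, warn = FALSE)
  A1 <- lifespan(T1, warn = FALSE)
  occupied <- which(grid$weights > 0)
  if (params$init == "overwinter") {
    age <- M1 + (seq_len(n_age) - 0.5) / n_age * (A1 - M1)
    bins <- rep(occupied, each = n_age)
    new_cohorts(
      bin = bins,
      site = rep(pref_mean(pref_dist_grid(grid)), length(bins)),
      density = rep(params$n_seed * grid$weights[occupied] / n_age,
                    each = n_age),
      dev = rep(1, length(bins)),
      sen = rep(age / A1, length(occupied)),
      adult = rep(TRUE, length(bins)))
  } else {
    new_cohorts(
      bin = occupied,
      site = rep(pref_mean(pref_dist_grid(grid)), length(occupied)),
      density = params$n_seed * grid$weights[occupied],
      dev = rep(0, length(occupied)),
      sen = rep(0, length(occupied)),
      adult = rep(FALSE, length(occupied)))
  }
}

#' Advance the cohort table by one day
#'
#' Deterministic analogue of [step_day()]: every cohort is scaled by the
#' survival factor `1 - delta`; cohorts accumulate development and
#' senescence at their own experienced temperature; cohorts whose
#' senescence reaches 1 are removed (thermal death), cohorts whose
#' development reaches 1 become adult; each preference bin's adult density
#' `A_k` lays an egg mass `beta * A_k`, placed in the parent bin (AT) or
#' spread across bins by the grid weights (BH) and split between sun and
#' shade sites in fractions `(p_k, 1 - p_k)` of the parent bin -- the
#' infinite-population limit of the agent model's Bernoulli draws.
#'
#' @param table A cohort table.
#' @param day Day index.
#' @param w A `weather_series`.
#' @param params A [model_params].
#' @param grid A [pref_grid].
#' @return List with the updated `table` and the day's `births`,
#'   `random_deaths`, `thermal_deaths` (densities).
#' @export
step_day_det <- function(table, day, w, params, grid) {
  T_day <- effective_temperature(w)[day]
  cloud <- w$cloud[day]
  if (!length(table$density))
    return(list(table = table, births = 0, random_deaths = 0,
                thermal_deaths = 0))

  total_before <- sum(table$density)
  table$density <- table$density * (1 - params$delta)
  random_deaths <- total_before - sum(table$density)

  p_bin <- grid$centers[table$bin]
  te <- numeric(length(p_bin))
  ad <- table$adult
  if (any(ad))
    te[ad] <- adult_experience(p_bin[ad], T_day, cloud, params)
  if (any(!ad)) {
    te[!ad] <- if (params$dev_site == "bernoulli") {
      thermal_experience(table$site[!ad], T_day, cloud, params$shadeDiff)
    } else {
      thermal_experience(p_bin[!ad], T_day, cloud, params$shadeDiff)
    }
  }
  inc <- daily_increments(te)
  table$dev[!ad] <- table$dev[!ad] + inc$dev_rate[!ad]
  table$sen <- table$sen + inc$sen_rate
  dead <- table$sen >= 1
  thermal_deaths <- sum(table$density[dead])
  if (any(dead)) table <- lapply(table, `[`, !dead)
  table$adult <- table$adult | table$dev >= 1

  K <- grid$K
  adult_by_bin <- numeric(K)
  if (any(table$adult)) {
    tab <- tapply(table$density[table$adult], table$bin[table$adult], sum)
    adult_by_bin[as.integer(names(tab))] <- tab
  }
  births <- 0
  if (params$beta > 0 && sum(adult_by_bin) > 0) {
    p_k <- grid$centers
    if (params$strategy == "AT") {
      egg_sun <- params$beta * adult_by_bin * p_k
      egg_shade <- params$beta * adult_by_bin * (1 - p_k)
    } else {
      egg_sun <- params$beta * sum(adult_by_bin * p_k) * grid$weights
      egg_shade <- params$beta * sum(adult_by_bin * (1 - p_k)) * grid$weights
    }
    keep_s <- egg_sun > 0
    keep_h <- egg_shade > 0
    nb <- sum(keep_s) + sum(keep_h)
    births <- sum(egg_sun) + sum(egg_shade)
    if (nb > 0) {
      newborn <- new_cohorts(
        bin = c(seq_len(K)[keep_s], seq_len(K)[keep_h]),
        site = c(rep(1, sum(keep_s)), rep(0, sum(keep_h))),
        density = c(egg_sun[keep_s], egg_shade[keep_h]),
        dev = numeric(nb), sen = numeric(nb), adult = logical(nb))
      table <- Map(c, table, newborn)
    }
  }
  list(table = table, births = births, random_deaths = random_deaths,
       thermal_deaths = thermal_deaths)
}

#' Run one breeding season of the difference-equation model
#'
#' Deterministic: repeated calls are bit-identical.  The optional abundance
#' surface records, per day, the total density in each preference bin.
#'
#' @param params A [model_params].
#' @param grid A [pref_grid] (101 bins by default elsewhere; convergence in
#'   `K` should be checked for new configurations).
#' @param w A `weather_series`.
#' @param n_age Seed age slices (see [init_density()]).
#' @param record_surface Record the preference-by-time abundance surface.
#' @param prune_tol Cohorts below this fraction of total density are
#'   dropped (0 = exact bookkeeping; small values speed up long runs at
#'   negligible cost to totals).
#' @return A `simulation_result` (as for [run_season()], with real-valued
#'   densities) plus `surface` (`K x (L + 1)` matrix) when requested.
#' @export
run_season_det <- function(params, grid, w, n_age = 25L,
                           record_surface = FALSE, prune_tol = 0) {
  stopifnot(inherits(w, "weather_series"))
  table <- init_density(params, grid, w, n_age = n_age)
  L <- nrow(w)
  daily_pop <- numeric(L + 1L)
  daily_adults <- numeric(L + 1L)
  daily_mean_p <- numeric(L + 1L)
  births <- numeric(L)
  rdeaths <- numeric(L)
  tdeaths <- numeric(L)
  surface <- if (record_surface) matrix(0, grid$K, L + 1L) else NULL

  snapshot <- function(slot) {
    daily_pop[slot] <<- sum(table$density)
    daily_adults[slot] <<- sum(table$density[table$adult])
    daily_mean_p[slot] <<- if (daily_pop[slot] > 0) {
      sum(grid$centers[table$bin] * table$density) / daily_pop[slot]
    } else NA_real_
    if (record_surface) {
      tab <- tapply(table$density, table$bin, sum)
      surface[as.integer(names(tab)), slot] <<- tab
    }
  }
  snapshot(1L)
  for (day in seq_len(L)) {
    st <- step_day_det(table, day, w, params, grid)
    table <- st$table
    births[day] <- st$births
    rdeaths[day] <- st$random_deaths
    tdeaths[day] <- st$thermal_deaths
    if (prune_tol > 0 && length(table$density)) {
      tiny <- table$density < prune_tol * sum(table$density)
      if (any(tiny)) table <- lapply(table, `[`, !tiny)
    }
    snapshot(day + 1L)
  }
  structure(list(daily_pop = daily_pop, daily_adults = daily_adults,
                 daily_mean_p = daily_mean_p, births = births,
                 random_deaths = rdeaths, thermal_deaths = tdeaths,
                 deaths_by_cause = c(random = sum(rdeaths),
                                     thermal = sum(tdeaths)),
                 fitness_ratio = daily_pop[L + 1L] / daily_pop[1L],
                 strategy = params$strategy, flavor = "det",
                 surface = surface, L = L),
            class = "simulation_result")
}
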