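# Stochastic individual-based implementation of the life-history model.
# The population is held as parallel vectors; each simulated day applies,
# in a fixed order: random death, development/senescence accumulation
# (with eclosion and thermal death), then reproduction.  Newborns join the
# population after the day's accumulation phase, so they begin developing
# the day after they are laid.

#' Initialize an agent population
#'
#' The default seeding emulates overwintered adults: `n_seed` flies with
#' preference drawn from the model's preference distribution and ages
#' uniform on `[M(T1), A(T1)]` at the day-1 temperature `T1` (senescence
#' progress `age / A(T1)`).  Each seed fly's developmental site (sun or
#' shade) is Bernoulli with probability equal to the distribution mean.
#' With `init = "egg"` the seed is synchronized to the egg stage instead.
#'
#' @param params A [model_params].
#' @param w A `weather_series`.
#' @param seed Integer seed.
#' @return A `fly_population`: list of parallel vectors `p`, `dev`, `sen`,
#'   `adult`, `in_sun`, `mother_p`.
#' @export
init_population <- function(params, w, seed = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(w, "weather_series"))
  if (nrow(w) < 1L) stop("weather series is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_seed
  T1 <- effective_temperature(w)[1L]
  M1 <- eclosion_time(T1, warn = FALSE)
  A1 <- lifespan(T1, warn = FALSE)
  if (M1 >= A1)
    stop("eclosion time at the day-1 temperature is not below lifespan",
         call. = FALSE)
  p <- rpref(n, params$pref_dist)
  if (params$init == "overwinter") {
    age <- stats::runif(n, M1, A1)
    pop <- list(p = p, dev = rep(1, n), sen = age / A1,
                adult = rep(TRUE, n),
                in_sun = stats::runif(n) < pref_mean(params$pref_dist),
                mother_p = rep(NA_real_, n))
  } else {
    pop <- list(p = p, dev = rep(0, n), sen = rep(0, n),
                adult = rep(FALSE, n),
                in_sun = stats::runif(n) < pref_mean(params$pref_dist),
                mother_p = rep(NA_real_, n))
  }
  structure(pop, class = "fly_population")
}

#' Advance the agent population by one day
#'
#' Phases, in order: (1) random death with probability `delta`;
#' (2) thermal experience per fly (adults behave with their own preference;
#' developing flies sit at their fixed sun/shade site, or follow their own
#' preference under `dev_site = "preference"`), rate-summation
#' accumulation, thermal death at senescence 1, eclosion at development 1;
#' (3) each surviving adult lays an egg with probability `beta`
#' (Bernoulli, or Poisson-many under `birth_model = "poisson"`); progeny
#' preference is the mother's (AT) or a fresh draw (BH), and the egg's
#' site is sunny with probability equal to the mother's preference.
#'
#' @param pop A `fly_population`.
#' @param day Day index into the weather series.
#' @param w A `weather_series`.
#' @param params A [model_params].
#' @return List with the updated `pop` and the day's tallies `births`,
#'   `random_deaths`, `thermal_deaths`.
#' @export
step_day <- function(pop, day, w, params) {
  n <- length(pop$p)
  T_day <- effective_temperature(w)[day]
  cloud <- w$cloud[day]
  if (n == 0L)
    return(list(pop = pop, births = 0L, random_deaths = 0L,
                thermal_deaths = 0L))

  # (1) random death
  survive <- stats::runif(n) >= params$delta
  random_deaths <- sum(!survive)
  pop <- lapply(pop, `[`, survive)
  n <- length(pop$p)

  # (2) accumulation, thermal death, eclosion
  if (n > 0L) {
    te <- numeric(n)
    ad <- pop$adult
    if (any(ad))
      te[ad] <- adult_experience(pop$p[ad], T_day, cloud, params)
    if (any(!ad)) {
      te[!ad] <- if (params$dev_site == "bernoulli") {
        thermal_experience(as.numeric(pop$in_sun[!ad]), T_day, cloud,
                           params$shadeDiff)
      } else {
        thermal_experience(pop$p[!ad], T_day, cloud, params$shadeDiff)
      }
    }
    inc <- daily_increments(te)
    pop$dev[!ad] <- pop$dev[!ad] + inc$dev_rate[!ad]
    pop$sen <- pop$sen + inc$sen_rate
    dead <- pop$sen >= 1
    thermal_deaths <- sum(dead)
    if (thermal_deaths > 0L) pop <- lapply(pop, `[`, !dead)
    pop$adult <- pop$adult | pop$dev >= 1
  } else {
    thermal_deaths <- 0L
  }

  # (3) reproduction
  n <- length(pop$p)
  births <- 0L
  if (n > 0L && params$beta > 0 && any(pop$adult)) {
    mothers <- which(pop$adult)
    n_eggs_per <- if (params$birth_model == "bernoulli") {
      stats::rbinom(length(mothers), 1L, min(params$beta, 1))
    } else {
      stats::rpois(length(mothers), params$beta)
    }
    mom <- rep(mothers, n_eggs_per)
    births <- length(mom)
    if (births > 0L) {
      mother_p <- pop$p[mom]
      child_p <- if (params$strategy == "AT") mother_p else
        rpref(births, params$pref_dist)
      newborn <- list(p = child_p, dev = rep(0, births),
                      sen = rep(0, births), adult = rep(FALSE, births),
                      in_sun = stats::runif(births) < mother_p,
                      mother_p = mother_p)
      pop <- Map(c, pop, newborn)
    }
  }
  class(pop) <- "fly_population"
  list(pop = pop, births = births, random_deaths = random_deaths,
       thermal_deaths = thermal_deaths)
}

#' Run one breeding season of the agent model
#'
#' @param params A [model_params].
#' @param w A `weather_series` covering the season.
#' @param seed Integer seed (initialization and all daily stochasticity).
#' @return A `simulation_result`: `daily_pop` and `daily_mean_p` (length
#'   `L + 1`, entry 1 being the seeded population before any day has run),
#'   `daily_adults`, per-day birth/death tallies, `deaths_by_cause`, and
#'   `fitness_ratio` (final population over seeded population; 0 on
#'   extinction).
#' @export
run_season <- function(params, w, seed = NULL) {
  stopifnot(inherits(w, "weather_series"))
  pop <- init_population(params, w, seed = seed)
  L <- nrow(w)
  daily_pop <- integer(L + 1L)
  daily_adults <- integer(L + 1L)
  daily_mean_p <- numeric(L + 1L)
  births <- integer(L)
  rdeaths <- integer(L)
  tdeaths <- integer(L)
  daily_pop[1L] <- length(pop$p)
  daily_adults[1L] <- sum(pop$adult)
  daily_mean_p[1L] <- mean(pop$p)
  for (day in seq_len(L)) {
    st <- step_day(pop, day, w, params)
    pop <- st$pop
    births[day] <- st$births
    rdeaths[day] <- st$random_deaths
    tdeaths[day] <- st$thermal_deaths
    daily_pop[day + 1L] <- length(pop$p)
    daily_adults[day + 1L] <- sum(pop$adult)
    daily_mean_p[day + 1L] <- if (length(pop$p)) mean(pop$p) else NA_real_
  }
  structure(list(daily_pop = daily_pop, daily_adults = daily_adults,
                 daily_mean_p = daily_mean_p, births = births,
                 random_deaths = rdeaths, thermal_deaths = tdeaths,
                 deaths_by_cause = c(random = sum(rdeaths),
                                     thermal = sum(tdeaths)),
                 fitness_ratio = daily_pop[L + 1L] / daily_pop[1L],
                 strategy = params$strategy, flavor = "agent",
                 L = L),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "%s season (%s model, %d days): %d -> %s flies, fitness ratio %.3f\n",
    x$strategy, x$flavor, x$L, round(x$daily_pop[1L]),
    format(round(x$daily_pop[x$L + 1L], 2)), x$fitness_ratio))
  cat(sprintf("  mean preference %.3f -> %.3f; deaths: %s random, %s thermal\n",
              x$daily_mean_p[1L], x$daily_mean_p[x$L + 1L],
              format(round(x$deaths_by_cause["random"], 2)),
              format(round(x$deaths_by_cause["thermal"], 2))))
  invisible(x)
}
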