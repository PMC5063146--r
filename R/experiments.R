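# Experiment suite: head-to-head BH-vs-AT comparisons, random-season
# ensembles and their predictors, multi-season accumulation, climate-offset
# and season-length sweeps, and variance/plasticity sweeps.  Weather is
# always shared between the BH and AT arms of a comparison (paired design).

season_summary <- function(w) {
  te <- effective_temperature(w)
  c(mean_temp = mean(te), sd_temp = stats::sd(te), length = nrow(w),
    mean_cloud = mean(w$cloud))
}

with_strategy <- function(params, strategy) {
  params$strategy <- strategy
  params
}

#' Compare the BH and AT strategies on one season
#'
#' Runs both strategies on the same weather and returns the end-of-season
#' advantage `(pop_BH - pop_AT) / pop_AT * 100`.  The deterministic flavor
#' runs each strategy once; the agent flavor averages final populations
#' over `reps` replicates (per-replicate seeds derived from `seed`) and
#' attaches a delta-method Monte-Carlo SE.
#'
#' @param w A `weather_series`.
#' @param params A [model_params] (its `strategy` field is overridden for
#'   each arm); should be calibrated for `w`.
#' @param flavor `"det"` or `"agent"`.
#' @param reps Agent replicates per strategy.
#' @param seed Integer root seed (agent flavor).
#' @param grid Preference grid for the deterministic flavor (defaults to
#'   101 bins of `params$pref_dist`).
#' @param n_age Seed age slices.
#' @return An `advantage_record`: `advantage_pct`, `se` (agent flavor),
#'   `final_bh`, `final_at`, `season` (summary stats), `flavor`,
#'   `at_extinct` flag (advantage is `NA` and flagged, not infinite, when
#'   the AT arm dies out).
#' @export
compare_strategies <- function(w, params, flavor = c("det", "agent"),
                               reps = 20L, seed = 1L, grid = NULL,
                               n_age = 25L) {
  stopifnot(inherits(w, "weather_series"), inherits(params, "model_params"))
  flavor <- match.arg(flavor)
  if (flavor == "det") {
    if (is.null(grid)) grid <- pref_grid(params$pref_dist, 101L)
    fin <- vapply(c("BH", "AT"), function(s) {
      run_season_det(with_strategy(params, s), grid, w, n_age = n_age,
                     prune_tol = 1e-12)$daily_pop[nrow(w) + 1L]
    }, numeric(1))
    se <- NA_real_
    finals_bh <- fin["BH"]; finals_at <- fin["AT"]
    m_bh <- fin["BH"]; m_at <- fin["AT"]
  } else {
    finals <- sapply(seq_len(reps), function(r) {
      c(BH = run_season(with_strategy(params, "BH"), w,
                        seed = derive_seed(seed, 2L * r))$daily_pop[nrow(w) + 1L],
        AT = run_season(with_strategy(params, "AT"), w,
                        seed = derive_seed(seed, 2L * r + 1L))$daily_pop[nrow(w) + 1L])
    })
    finals_bh <- finals["BH", ]; finals_at <- finals["AT", ]
    m_bh <- mean(finals_bh); m_at <- mean(finals_at)
    se <- if (m_at > 0) {
      100 * sqrt(stats::var(finals_bh) / reps / m_at^2 +
                   m_bh^2 * stats::var(finals_at) / reps / m_at^4)
    } else NA_real_
  }
  at_extinct <- m_at <= 0
  structure(list(
    advantage_pct = if (at_extinct) NA_real_ else
      unname((m_bh - m_at) / m_at * 100),
    se = unname(se), final_bh = unname(m_bh), final_at = unname(m_at),
    season = season_summary(w), flavor = flavor, at_extinct = at_extinct,
    seed = if (flavor == "agent") seed else NULL),
    class = "advantage_record")
}

#' @export
print.advantage_record <- function(x, ...) {
  if (x$at_extinct) {
    cat("BH vs AT: AT arm extinct (advantage undefined)\n")
  } else {
    cat(sprintf("BH vs AT advantage: %+.3f%%%s  (%s flavor; season mean %.1f C)\n",
                x$advantage_pct,
                if (is.finite(x$se)) sprintf(" +/- %.3f", x$se) else "",
                x$flavor, x$season["mean_temp"]))
  }
  invisible(x)
}

#' BH-vs-AT advantage across an ensemble of random seasons
#'
#' Each season draws fresh AR temperature deviations (and optionally a
#' cloud surrogate) from the weather model; both strategies run on the same
#' season (deterministic flavor).  The summary reports the fraction of
#' seasons in which BH wins and quadratic fits of advantage against season
#' mean temperature and temperature SD.
#'
#' @param n_seasons Number of random seasons.
#' @param weather_model A `weather_model` (see [boston_weather_model()]).
#' @param params Calibrated [model_params].
#' @param seed Integer root seed.
#' @param grid Preference grid (defaults to 101 bins).
#' @param cloud Include cloud surrogates.
#' @param n_age Seed age slices.
#' @return List with `records` (one row per season: advantage and season
#'   stats), `frac_bh` (fraction with positive advantage), and `fits`
#'   (quadratic fits vs `mean_temp` and `sd_temp`, each with `coef` and
#'   `r2`).
#' @export
ensemble_random_seasons <- function(n_seasons, weather_model, params,
                                    seed = 1L, grid = NULL, cloud = TRUE,
                                    n_age = 25L) {
  if (is.null(grid)) grid <- pref_grid(params$pref_dist, 101L)
  rows <- lapply(seq_len(n_seasons), function(i) {
    w <- random_season(weather_model, seed = derive_seed(seed, i),
                       cloud = cloud)
    rec <- compare_strategies(w, params, flavor = "det", grid = grid,
                              n_age = n_age)
    data.frame(season = i, advantage_pct = rec$advantage_pct,
               mean_temp = rec$season["mean_temp"],
               sd_temp = rec$season["sd_temp"],
               mean_cloud = rec$season["mean_cloud"])
  })
  records <- do.call(rbind, c(rows, make.row.names = FALSE))
  quad_fit <- function(xname) {
    f <- stats::lm(records$advantage_pct ~ stats::poly(records[[xname]], 2,
                                                       raw = TRUE))
    list(coef = unname(stats::coef(f)), r2 = summary(f)$r.squared)
  }
  list(records = records,
       frac_bh = mean(records$advantage_pct > 0),
       fits = if (n_seasons >= 4) {
         list(mean_temp = quad_fit("mean_temp"),
              sd_temp = quad_fit("sd_temp"))
       } else NULL)
}

#' Cumulative BH-vs-AT advantage across sequential seasons
#'
#' Per-season fitness-ratio quotients (BH over AT) compound
#' multiplicatively; seasons are independent draws from the weather model
#' (populations reset each season -- overwintering dynamics are outside
#' the model).
#'
#' @inheritParams ensemble_random_seasons
#' @return Data frame with per-season `advantage_pct` and the `cumulative`
#'   multiplicative BH:AT factor.
#' @export
multi_season_accumulation <- function(n_seasons, weather_model, params,
                                      seed = 1L, grid = NULL, cloud = TRUE,
                                      n_age = 25L) {
  ens <- ensemble_random_seasons(n_seasons, weather_model, params,
                                 seed = seed, grid = grid, cloud = cloud,
                                 n_age = n_age)
  data.frame(season = ens$records$season,
             advantage_pct = ens$records$advantage_pct,
             cumulative = cumprod(1 + ens$records$advantage_pct / 100))
}

#' BH-vs-AT advantage under mean-temperature offsets
#'
#' Applies each offset to the season with [transform_season()] and
#' re-compares the strategies; by default the calibrated `(beta, delta)`
#' are held fixed (a sudden-change scenario), with `recalibrate = TRUE`
#' refitting them per offset.  The zero-crossing offset -- the warming at
#' which AT overtakes BH -- is estimated by linear interpolation of the
#' advantage curve.
#'
#' @param offsets Numeric offsets (C).
#' @param w Baseline `weather_series`.
#' @param params Calibrated [model_params].
#' @param grid Preference grid.
#' @param recalibrate Refit `(beta, delta)` per offset.
#' @param n_age Seed age slices.
#' @param ... Passed to [fit_birth_death()] when recalibrating.
#' @return List with `records` (offset, advantage) and `crossing_offset`
#'   (first interpolated sign change, `NA` if none).
#' @export
climate_offset_sweep <- function(offsets, w, params, grid = NULL,
                                 recalibrate = FALSE, n_age = 25L, ...) {
  if (is.null(grid)) grid <- pref_grid(params$pref_dist, 101L)
  rows <- lapply(offsets, function(off) {
    wo <- transform_season(w, offset = off)
    po <- params
    if (recalibrate) {
      fit <- fit_birth_death(wo, grid, params, ...)
      po$beta <- fit$beta
      po$delta <- fit$delta
    }
    rec <- compare_strategies(wo, po, flavor = "det", grid = grid,
                              n_age = n_age)
    data.frame(offset = off, advantage_pct = rec$advantage_pct,
               mean_temp = rec$season["mean_temp"])
  })
  records <- do.call(rbind, c(rows, make.row.names = FALSE))
  ord <- order(records$offset)
  adv <- records$advantage_pct[ord]
  off <- records$offset[ord]
  crossing <- NA_real_
  for (i in seq_len(length(adv) - 1)) {
    if (is.finite(adv[i]) && is.finite(adv[i + 1]) &&
        sign(adv[i]) * sign(adv[i + 1]) < 0) {
      crossing <- off[i] + (0 - adv[i]) / (adv[i + 1] - adv[i]) *
        (off[i + 1] - off[i])
      break
    }
  }
  list(records = records, crossing_offset = crossing)
}

#' BH-vs-AT advantage versus breeding-season length
#'
#' Random seasons are compressed or stretched to each target length (the
#' histories, not their statistics, are rescaled) and the two strategies
#' compared per season.
#'
#' @param lengths Target season lengths in days (each in `[2, 366]`).
#' @param weather_model A `weather_model`.
#' @param params Calibrated [model_params].
#' @param n_per_length Random seasons per length.
#' @param seed Integer root seed.
#' @param grid Preference grid.
#' @param cloud Include cloud surrogates.
#' @param n_age Seed age slices.
#' @return List with `records` (per season) and `by_length` (mean and
#'   variance of advantage per length).
#' @export
season_length_sweep <- function(lengths, weather_model, params,
                                n_per_length = 10L, seed = 1L, grid = NULL,
                                cloud = TRUE, n_age = 25L) {
  if (is.null(grid)) grid <- pref_grid(params$pref_dist, 101L)
  rows <- list()
  for (li in seq_along(lengths)) {
    for (r in seq_len(n_per_length)) {
      w <- random_season(weather_model,
                         seed = derive_seed(seed, 1000L * li + r),
                         cloud = cloud)
      wl <- transform_season(w, stretch_to = lengths[li])
      rec <- compare_strategies(wl, params, flavor = "det", grid = grid,
                                n_age = n_age)
      rows[[length(rows) + 1L]] <- data.frame(
        length = lengths[li], rep = r, advantage_pct = rec$advantage_pct)
    }
  }
  records <- do.call(rbind, c(rows, make.row.names = FALSE))
  by_length <- do.call(rbind, lapply(split(records, records$length),
                                     function(d) data.frame(
                                       length = d$length[1],
                                       mean_adv = mean(d$advantage_pct),
                                       var_adv = stats::var(d$advantage_pct))))
  list(records = records, by_length = by_length[order(by_length$length), ])
}

#' End-of-season performance versus preference-distribution spread
#'
#' Scales the SD of the preference distribution (mean held fixed) and
#' records each strategy's end-of-season population, probing whether
#' intermediate levels of variability perform best.  Scale factors whose
#' implied SD is infeasible for a beta distribution are skipped with a
#' warning.
#'
#' @param scale_factors Multipliers on the baseline preference SD
#'   (0 = no variability).
#' @param params Calibrated [model_params]; its `pref_dist` supplies the
#'   baseline mean and SD.
#' @param w A `weather_series`.
#' @param grid_K Bins used for each scaled grid.
#' @param n_age Seed age slices.
#' @return Data frame with `scale`, `sd`, `strategy`, `final_pop`.
#' @export
variance_sweep <- function(scale_factors, params, w, grid_K = 101L,
                           n_age = 25L) {
  m <- pref_mean(params$pref_dist)
  s0 <- pref_sd(params$pref_dist)
  rows <- list()
  for (sc in scale_factors) {
    dist <- tryCatch(pref_dist_from_moments(m, sc * s0),
                     error = function(e) NULL)
    if (is.null(dist)) {
      warning(sprintf("scale %.3g gives an infeasible SD; skipped", sc),
              call. = FALSE)
      next
    }
    grid <- pref_grid(dist, grid_K)
    for (s in c("BH", "AT")) {
      pp <- with_strategy(params, s)
      pp$pref_dist <- dist
      r <- run_season_det(pp, grid, w, n_age = n_age, prune_tol = 1e-12)
      rows[[length(rows) + 1L]] <- data.frame(
        scale = sc, sd = sc * s0, strategy = s,
        final_pop = r$daily_pop[nrow(w) + 1L])
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' BH-vs-AT advantage under a concurrent plasticity strategy
#'
#' Each strength `lambda` lets every adult close that fraction of the gap
#' between its realized thermal experience and a fixed target temperature
#' (default 25 C), within the sun/shade band available that day; the two
#' inheritance strategies are then compared as usual.  `lambda = 0` is the
#' baseline model.
#'
#' @param strengths Plasticity strengths in \[0, 1\].
#' @param params Calibrated [model_params].
#' @param w A `weather_series`.
#' @param grid Preference grid.
#' @param target Preferred temperature of the overlay (C).
#' @param n_age Seed age slices.
#' @return Data frame with `lambda` and `advantage_pct`.
#' @export
plasticity_sweep <- function(strengths, params, w, grid = NULL,
                             target = 25, n_age = 25L) {
  if (is.null(grid)) grid <- pref_grid(params$pref_dist, 101L)
  rows <- lapply(strengths, function(lam) {
    pl <- params
    pl$plasticity_lambda <- lam
    pl$plasticity_target <- target
    rec <- compare_strategies(w, pl, flavor = "det", grid = grid,
                              n_age = n_age)
    data.frame(lambda = lam, advantage_pct = rec$advantage_pct)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
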