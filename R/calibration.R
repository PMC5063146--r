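# Equilibrium calibration of the daily birth and death probabilities.
# (beta, delta) are the unique pair for which, under the adaptive-tracking
# difference-equation model on the given weather, (1) the population
# neither grows nor shrinks over the season and (2) the mean thermal
# preference index does not evolve.

#' Fit (beta, delta) to the two seasonal equilibrium assumptions
#'
#' Residuals are `log(fitness_ratio)` (population stationarity) and
#' `mean_p(end) - mean_p(start)` (non-evolving preference), both evaluated
#' with the AT difference model, which the calibration always uses (it is
#' deterministic and, unlike BH, exposes selection on preference).
#'
#' `method = "grid_search"` exploits the structure of the system:
#' `log(fitness_ratio)` is strictly increasing in `beta`, so for each
#' `delta` a 1-D root find yields the `beta(delta)` restoring population
#' stationarity; the preference drift is then scanned along that curve for
#' a sign change and polished by a second 1-D root find.
#' `method = "hill_climb"` minimizes the squared residual norm by
#' Nelder-Mead from the middle of the search box.
#'
#' @param w A `weather_series`.
#' @param grid A [pref_grid] (moderate `K`, e.g. 31-51, is ample: the
#'   fitted point moves by less than the tolerances under refinement).
#' @param base_params A [model_params] supplying everything but
#'   `beta`/`delta` (its `strategy` is ignored; AT is used).
#' @param tol_pop Tolerance on `|fitness_ratio - 1|` (default 0.01).
#' @param tol_pref Tolerance on the absolute mean-preference drift
#'   (default 0.005).
#' @param method `"grid_search"` (default) or `"hill_climb"`.
#' @param beta_range,delta_range Search box.
#' @param n_delta Points of the outer delta scan.
#' @param n_age Seed age slices passed to the difference model.
#' @return List with `beta`, `delta`, `fitness_ratio`, `pref_drift`,
#'   `converged`, and `diagnostics` (the delta-scan residual table).
#'   If the drift never changes sign inside the box an error carrying the
#'   residual table is raised.
#' @export
fit_birth_death <- function(w, grid, base_params, tol_pop = 0.01,
                            tol_pref = 0.005,
                            method = c("grid_search", "hill_climb"),
                            beta_range = c(0.005, 0.4),
                            delta_range = c(0.005, 0.15),
                            n_delta = 7L, n_age = 15L) {
  stopifnot(inherits(w, "weather_series"), inherits(grid, "pref_grid"),
            inherits(base_params, "model_params"))
  if (tol_pop <= 0 || tol_pref <= 0)
    stop("tolerances must be positive", call. = FALSE)
  method <- match.arg(method)

  at_params <- function(beta, delta) {
    p <- base_params
    p$beta <- beta
    p$delta <- delta
    p$strategy <- "AT"
    p
  }
  run <- function(beta, delta) {
    run_season_det(at_params(beta, delta), grid, w, n_age = n_age,
                   prune_tol = 1e-12)
  }
  residuals_at <- function(beta, delta) {
    r <- run(beta, delta)
    c(log_fr = log(r$fitness_ratio),
      drift = r$daily_mean_p[r$L + 1L] - r$daily_mean_p[1L])
  }
  # seasonal log fitness is steep in beta (it compounds daily over the
  # whole season), so the root is resolved to 1e-6 on the beta scale; a
  # warm-start bracket from the previous delta keeps the cost down
  beta_for <- function(delta, bracket = beta_range) {
    f <- function(b) log(run(b, delta)$fitness_ratio)
    lo <- f(bracket[1]); hi <- f(bracket[2])
    if (lo > 0 || hi < 0) {
      bracket <- beta_range
      lo <- f(bracket[1]); hi <- f(bracket[2])
    }
    if (lo > 0 || hi < 0)
      stop(sprintf(
        "no beta in [%g, %g] balances the population at delta = %g",
        beta_range[1], beta_range[2], delta), call. = FALSE)
    stats::uniroot(f, bracket, f.lower = lo, f.upper = hi,
                   tol = 1e-6)$root
  }

  if (method == "grid_search") {
    deltas <- seq(delta_range[1], delta_range[2], length.out = n_delta)
    prev_b <- NA_real_
    scan <- lapply(deltas, function(d) {
      # deltas too high for any beta in the box to balance are recorded as
      # infeasible rather than aborting the whole scan
      bracket <- if (is.na(prev_b)) beta_range else
        c(max(beta_range[1], 0.8 * prev_b), min(beta_range[2], 2 * prev_b))
      b <- tryCatch(beta_for(d, bracket), error = function(e) NA_real_)
      if (is.na(b))
        return(data.frame(delta = d, beta = NA_real_,
                          log_fitness = NA_real_, pref_drift = NA_real_))
      prev_b <<- b
      res <- residuals_at(b, d)
      data.frame(delta = d, beta = b, log_fitness = res["log_fr"],
                 pref_drift = res["drift"])
    })
    scan <- do.call(rbind, c(scan, make.row.names = FALSE))
    sgn <- sign(scan$pref_drift)
    cross <- which(sgn[-1] * sgn[-n_delta] <= 0 &
                     !is.na(sgn[-1]) & !is.na(sgn[-n_delta]))
    if (!length(cross)) {
      cond <- simpleError(
        "preference drift does not change sign inside the delta search box")
      cond$diagnostics <- scan
      stop(cond)
    }
    i <- cross[1L]
    bb <- range(scan$beta[c(i, i + 1L)])
    drift_of <- function(d) residuals_at(beta_for(d, bb), d)["drift"]
    delta <- stats::uniroot(drift_of, c(scan$delta[i], scan$delta[i + 1L]),
                            f.lower = scan$pref_drift[i],
                            f.upper = scan$pref_drift[i + 1L],
                            tol = tol_pref / 10)$root
    beta <- beta_for(delta, bb)
  } else {
    obj <- function(par) {
      b <- exp(par[1]); d <- stats::plogis(par[2]) * delta_range[2]
      res <- residuals_at(b, d)
      (res["log_fr"] / tol_pop)^2 + (res["drift"] / tol_pref)^2
    }
    start <- c(log(mean(beta_range)),
               stats::qlogis(mean(delta_range) / delta_range[2]))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    beta <- exp(fit$par[1])
    delta <- stats::plogis(fit$par[2]) * delta_range[2]
    deltas <- delta
    scan <- NULL
  }

  final <- run(beta, delta)
  drift <- final$daily_mean_p[final$L + 1L] - final$daily_mean_p[1L]
  converged <- abs(final$fitness_ratio - 1) <= tol_pop &&
    abs(drift) <= tol_pref
  if (!converged)
    warning(sprintf(
      "calibration residuals exceed tolerance: |fr - 1| = %.3g, |drift| = %.3g",
      abs(final$fitness_ratio - 1), abs(drift)), call. = FALSE)
  list(beta = beta, delta = delta, fitness_ratio = final$fitness_ratio,
       pref_drift = drift, converged = converged,
       diagnostics = if (method == "grid_search") scan else NULL)
}
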