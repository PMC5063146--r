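# Temperature-dependent fly biology shared by the agent-based and
# difference-equation models: eclosion time M(T), lifespan A(T), the
# thermal-experience formula, and the rate-summation daily increments.

.lh <- new.env(parent = emptyenv())

lh_curves <- function() {
  if (is.null(.lh$eclosion)) {
    ecl <- utils::read.csv(system.file("extdata",
                                       "eclosion_time_synthetic.csv",
                                       package = "flybet"),
                           comment.char = "#")
    lsp <- utils::read.csv(system.file("extdata", "lifespan_synthetic.csv",
                                       package = "flybet"),
                           comment.char = "#")
    .lh$domain <- range(c(ecl$temperature_C, lsp$temperature_C))
    # monotone piecewise-cubic interpolation.  The eclosion curve is
    # V-shaped, so it is interpolated as two monotone pieces glued at the
    # minimum knot: each piece cannot over- or undershoot, which keeps the
    # interior minimum exactly at the 25 C knot.
    imin <- which.min(ecl$days)
    .lh$ecl_tmin <- ecl$temperature_C[imin]
    left <- stats::splinefun(ecl$temperature_C[seq_len(imin)],
                             ecl$days[seq_len(imin)], method = "monoH.FC")
    right <- stats::splinefun(ecl$temperature_C[imin:nrow(ecl)],
                              ecl$days[imin:nrow(ecl)], method = "monoH.FC")
    tmin <- .lh$ecl_tmin
    .lh$eclosion <- function(T) ifelse(T <= tmin, left(T), right(T))
    .lh$lifespan <- stats::splinefun(lsp$temperature_C, lsp$days,
                                     method = "monoH.FC")
  }
  .lh
}

clamp_temperature <- function(T, warn = TRUE) {
  env <- lh_curves()
  lo <- env$domain[1]; hi <- env$domain[2]
  out <- pmin(pmax(T, lo), hi)
  if (warn && any(T < lo | T > hi, na.rm = TRUE))
    warning(sprintf("temperature(s) clamped to the life-curve domain [%g, %g] C",
                    lo, hi), call. = FALSE)
  out
}

#' Egg-to-adult development time M(T)
#'
#' Interpolated from a packaged table of constant-temperature development
#' times (see `inst/extdata/eclosion_time_synthetic.csv`); development is
#' fastest at 25 C and slows toward both ends of the 12-32 C domain.
#' Temperatures outside the domain are clamped (with a warning unless
#' `warn = FALSE`).
#'
#' @param T Temperature(s) in C.
#' @param warn Warn when clamping.
#' @return Days to eclosion (positive).
#' @export
eclosion_time <- function(T, warn = TRUE) {
  lh_curves()$eclosion(clamp_temperature(T, warn))
}

#' Temperature-dependent lifespan A(T)
#'
#' Interpolated from a packaged table of constant-temperature mean
#' lifespans (egg-origin, so the adult seed-age interval `[M(T), A(T)]` is
#' nonempty); strictly decreasing in temperature over the domain.
#'
#' @inheritParams eclosion_time
#' @return Mean lifespan in days.
#' @export
lifespan <- function(T, warn = TRUE) {
  lh_curves()$lifespan(clamp_temperature(T, warn))
}

#' @rdname eclosion_time
#' @return `life_curve_domain` returns the interpolation domain (C).
#' @export
life_curve_domain <- function() lh_curves()$domain

#' Daily thermal experience of a fly
#'
#' A fly with thermal preference index `p` on a day with in-shade
#' temperature `T_day` and mean cloud cover `cloud` experiences
#' `T_day + p * shadeDiff * (1 - cloud)`: clouds reduce the sun/shade
#' temperature difference available to behavioral choice in proportion to
#' the cloudy fraction of the day.
#'
#' @param p Preference index in \[0, 1\] (0 = always shade).
#' @param T_day In-shade temperature (C).
#' @param cloud Cloud-cover fraction in \[0, 1\].
#' @param shadeDiff Clear-sky sun/shade temperature difference (C),
#'   default 7.
#' @return Experienced temperature (C); linear and nondecreasing in `p`,
#'   nonincreasing in `cloud`.
#' @export
thermal_experience <- function(p, T_day, cloud = 0, shadeDiff = 7) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(cloud < 0 | cloud > 1))
    stop("`cloud` must lie in [0, 1]", call. = FALSE)
  T_day + p * shadeDiff * (1 - cloud)
}

#' Daily development and senescence increments (rate summation)
#'
#' Under varying temperatures, development and senescence accumulate
#' reciprocally: a day at experienced temperature `T_exp` contributes
#' `1/M(T_exp)` toward eclosion (complete at 1) and `1/A(T_exp)` toward
#' thermal-experience-dependent death (death at 1, counted from the egg
#' stage).  At constant temperature this reproduces the life curves
#' exactly.
#'
#' @param T_exp Experienced temperature(s) (C); clamped to the life-curve
#'   domain.
#' @return List with `dev_rate` and `sen_rate` (1/days).
#' @export
daily_increments <- function(T_exp) {
  Tc <- clamp_temperature(T_exp, warn = FALSE)
  env <- lh_curves()
  list(dev_rate = 1 / env$eclosion(Tc), sen_rate = 1 / env$lifespan(Tc))
}

#' Life-history model parameters
#'
#' @param beta Daily per-adult birth probability (`>= 0`).
#' @param delta Daily random (non-thermal) death probability in \[0, 1\].
#' @param shadeDiff Clear-sky sun/shade temperature difference (C),
#'   default 7.
#' @param pref_dist Preference distribution ([pref_dist]), default the
#'   fitted Beta(mean 0.32, SD 0.13).
#' @param strategy `"BH"` (each birth draws a fresh preference from
#'   `pref_dist`) or `"AT"` (progeny inherit the mother's preference
#'   exactly).
#' @param n_seed Seed population size (default 100 adults).
#' @param birth_model `"bernoulli"` (default; at most one egg per mother
#'   per day) or `"poisson"`.
#' @param dev_site `"bernoulli"`: an egg develops entirely in sun or shade,
#'   chosen once with probability equal to the mother's preference;
#'   `"preference"`: developmental temperature follows the progeny's own
#'   preference index.
#' @param init `"overwinter"` (default; seed adults with ages uniform on
#'   `[M(T1), A(T1)]`) or `"egg"` (seed synchronized to the egg stage).
#' @param plasticity_lambda Strength in \[0, 1\] of a behavioral-plasticity
#'   overlay: each adult closes this fraction of the gap between its
#'   realized thermal experience and `plasticity_target`, limited to the
#'   attainable band `[T_day, T_day + shadeDiff * (1 - cloud)]`.  0 (the
#'   default) disables the overlay.
#' @param plasticity_target Preferred temperature of the plasticity overlay
#'   (C), default 25 (the development optimum).
#' @return A `model_params` list.
#' @export
model_params <- function(beta, delta, shadeDiff = 7,
                         pref_dist = default_pref_dist(),
                         strategy = c("BH", "AT"), n_seed = 100L,
                         birth_model = c("bernoulli", "poisson"),
                         dev_site = c("bernoulli", "preference"),
                         init = c("overwinter", "egg"),
                         plasticity_lambda = 0, plasticity_target = 25) {
  strategy <- match.arg(strategy)
  birth_model <- match.arg(birth_model)
  dev_site <- match.arg(dev_site)
  init <- match.arg(init)
  if (beta < 0) stop("`beta` must be nonnegative", call. = FALSE)
  if (delta < 0 || delta > 1)
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  if (shadeDiff < 0) stop("`shadeDiff` must be nonnegative", call. = FALSE)
  if (plasticity_lambda < 0 || plasticity_lambda > 1)
    stop("`plasticity_lambda` must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(pref_dist, "pref_dist"))
  structure(list(beta = beta, delta = delta, shadeDiff = shadeDiff,
                 pref_dist = pref_dist, strategy = strategy,
                 n_seed = as.integer(n_seed), birth_model = birth_model,
                 dev_site = dev_site, init = init,
                 plasticity_lambda = plasticity_lambda,
                 plasticity_target = plasticity_target),
            class = "model_params")
}

# Adult thermal experience for a vector of preferences, with the optional
# plasticity overlay (fraction lambda of the gap to the target closed,
# clipped to the attainable sun/shade band).
adult_experience <- function(p, T_day, cloud, params) {
  te <- thermal_experience(p, T_day, cloud, params$shadeDiff)
  if (params$plasticity_lambda > 0) {
    band_hi <- T_day + params$shadeDiff * (1 - cloud)
    te <- te + params$plasticity_lambda * (params$plasticity_target - te)
    te <- pmin(pmax(te, T_day), band_hi)
  }
  te
}
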