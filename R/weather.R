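# Daily seasonal weather: baseline (climate-normal) temperature, deviations
# from normal, and cloud-cover fraction, plus generators for synthetic
# seasons (AR-filtered deviations, autocorrelation-preserving cloud
# surrogates).

#' Construct a weather series
#'
#' @param t_normal Baseline in-shade temperature per day (C).
#' @param deviation Daily deviation from normal (C), default 0.
#' @param cloud Daily mean cloud-cover fraction in \[0, 1\], default 0.
#' @param offset Global temperature offset (C) applied on top of baseline
#'   and deviation, default 0.
#' @return A `weather_series`: data frame with columns `day`, `t_normal`,
#'   `deviation`, `cloud` and an `offset` attribute.  The effective in-shade
#'   temperature on day j is `t_normal + deviation + offset`.
#' @export
weather_series <- function(t_normal, deviation = 0, cloud = 0, offset = 0) {
  L <- length(t_normal)
  deviation <- rep_len(deviation, L)
  cloud <- rep_len(cloud, L)
  if (any(!is.finite(t_normal)) || any(!is.finite(deviation)))
    stop("temperatures must be finite", call. = FALSE)
  if (any(cloud < 0 | cloud > 1))
    stop("cloud fractions must lie in [0, 1]", call. = FALSE)
  structure(data.frame(day = seq_len(L), t_normal = t_normal,
                       deviation = deviation, cloud = cloud),
            offset = offset,
            class = c("weather_series", "data.frame"))
}

#' @rdname weather_series
#' @param w A `weather_series`.
#' @return `effective_temperature` returns the per-day in-shade temperature
#'   `t_normal + deviation + offset` (C).
#' @export
effective_temperature <- function(w) {
  stopifnot(inherits(w, "weather_series"))
  w$t_normal + w$deviation + attr(w, "offset")
}

#' @export
print.weather_series <- function(x, ...) {
  te <- effective_temperature(x)
  cat(sprintf(
    "Weather series: %d days, mean %.1f C (range %.1f-%.1f), mean cloud %.2f, offset %+.1f C\n",
    nrow(x), mean(te), min(te), max(te), mean(x$cloud), attr(x, "offset")))
  invisible(x)
}

#' Read a daily weather series from CSV
#'
#' Expected columns: `date` (contiguous calendar days), `t_normal` (C), and
#' optionally `deviation` (C) and `cloud` (fraction); absent optional
#' columns default to zero with a message.
#'
#' @param path CSV file path.
#' @return A `weather_series`.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("date", "t_normal") %in% names(df)))
    stop("weather CSV needs columns `date` and `t_normal`", call. = FALSE)
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable dates in weather CSV", call. = FALSE)
  gaps <- which(diff(as.integer(dates)) != 1L)
  if (length(gaps))
    stop(sprintf("dates not contiguous after row(s): %s",
                 paste(gaps, collapse = ", ")), call. = FALSE)
  if (is.null(df$deviation)) {
    message("no `deviation` column: assuming zero deviations")
    df$deviation <- 0
  }
  if (is.null(df$cloud)) {
    message("no `cloud` column: assuming clear skies")
    df$cloud <- 0
  }
  bad <- which(df$cloud < 0 | df$cloud > 1)
  if (length(bad))
    stop(sprintf("cloud fraction outside [0, 1] in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  weather_series(df$t_normal, df$deviation, df$cloud)
}

#' Write a weather series to CSV
#'
#' @param w A `weather_series`.
#' @param path File path.
#' @param start Calendar date of day 1 (the default April 1 matches the
#'   modeled breeding season).
#' @export
write_weather <- function(w, path, start = as.Date("2000-04-01")) {
  stopifnot(inherits(w, "weather_series"))
  utils::write.csv(
    data.frame(date = start + w$day - 1L,
               t_normal = w$t_normal + attr(w, "offset"),
               deviation = w$deviation, cloud = w$cloud),
    path, row.names = FALSE)
  invisible(path)
}

#' Synthetic seasonal climate normals
#'
#' A smooth stand-in for a mid-latitude breeding-season baseline: the
#' temperature rises along a quarter sinusoid from `T_start` (day 1) to
#' `T_peak` (day `peak_day`) and descends symmetrically back to `T_start`
#' by day `L`.  The defaults approximate a Boston-like season of 214 days
#' (April 1 - October 31): ~7 C at the season edges, ~23.5 C at the
#' mid-July peak.
#'
#' @param L Season length in days (`>= 2`).
#' @param T_start,T_peak Edge and peak baseline temperatures (C); equal
#'   values produce the constant-weather control.
#' @param peak_day Day of the peak, inside `[1, L]`.
#' @return A `weather_series` with zero deviations and clear skies.
#' @export
synthetic_normals <- function(L = 214L, T_start = 7, T_peak = 23.5,
                              peak_day = NULL) {
  if (L < 2L) stop("`L` must be at least 2", call. = FALSE)
  # default peak a little past midseason (day 115 of 214, mid-July for an
  # April 1 start)
  if (is.null(peak_day)) peak_day <- max(1L, round(115 / 214 * L))
  if (peak_day < 1L || peak_day > L)
    stop("`peak_day` must lie in [1, L]", call. = FALSE)
  j <- seq_len(L)
  phase <- ifelse(j <= peak_day,
                  (j - 1) / max(peak_day - 1, 1),
                  1 + (j - peak_day) / max(L - peak_day, 1))
  t_normal <- T_start + (T_peak - T_start) * sin(pi / 2 * phase)
  weather_series(t_normal)
}

#' Fit an autoregressive model to historical temperature deviations
#'
#' Daily deviations from climate normals are close to normally distributed;
#' they are modeled as an AR process (default order 30) of Gaussian white
#' noise, fitted by Yule-Walker.  The innovation SD is stored as the
#' (implied) extra parameter, and stationarity of the fitted filter is
#' checked via the characteristic roots.
#'
#' @param deviations Historical deviation series (C), length at least
#'   `10 * order`.
#' @param order AR order (default 30).
#' @return An `ar_model`: `coefficients` (length `order`),
#'   `innovation_sd`, `order`, `stationary`.
#' @export
fit_ar <- function(deviations, order = 30L) {
  if (length(deviations) < 10L * order)
    stop(sprintf(
      "series length %d < 10 x order; supply more data or a lower order",
      length(deviations)), call. = FALSE)
  fit <- stats::ar(deviations, aic = FALSE, order.max = order,
                   method = "yule-walker", demean = TRUE)
  coefs <- as.numeric(fit$ar)
  roots <- polyroot(c(1, -coefs))
  structure(list(coefficients = coefs,
                 innovation_sd = sqrt(fit$var.pred),
                 order = order,
                 stationary = all(Mod(roots) > 1)),
            class = "ar_model")
}

#' Simulate a deviation series from a fitted AR model
#'
#' Gaussian innovations are filtered through the AR weights; a burn-in of
#' `10 * order` days is discarded so the returned series is (approximately)
#' stationary from day 1.
#'
#' @param model An `ar_model`.
#' @param L Days to return.
#' @param seed Integer seed.
#' @param force Simulate even if the fitted filter is non-stationary.
#' @return Numeric deviation series of length `L` (C).
#' @export
simulate_deviations <- function(model, L, seed = NULL, force = FALSE) {
  stopifnot(inherits(model, "ar_model"))
  if (!model$stationary && !force)
    stop("AR model is non-stationary; pass force = TRUE to simulate anyway",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (model$innovation_sd == 0) return(numeric(L))
  burn <- 10L * model$order
  e <- stats::rnorm(L + burn, 0, model$innovation_sd)
  x <- stats::filter(e, model$coefficients, method = "recursive")
  as.numeric(utils::tail(x, L))
}

acf_vector <- function(x, lag_max = 30L) {
  as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
}

#' Constrained cloud-cover surrogate
#'
#' Draws a season of cloud fractions from the empirical distribution of a
#' historical series and rearranges it so that (i) the surrogate is
#' decorrelated from the original series (`|r| < max_corr`) while (ii) its
#' autocorrelation function (lags 1..`lag_max`) stays correlated with the
#' historical ACF at `r > min_acf_match` -- i.e. the marginal distribution
#' and the temporal structure of cloudiness are preserved but the actual
#' day-to-day history is new.  The rearrangement is a constrained pair-swap
#' anneal initialized from a rank-remapped Gaussian AR surrogate.
#'
#' @param historical_cloud Historical cloud fractions (length `>= L`).
#' @param L Season length.
#' @param max_corr Decorrelation bound (default 0.1).
#' @param min_acf_match ACF-match bound (default 0.998).
#' @param seed Integer seed.
#' @param max_iter Swap-proposal budget.
#' @param lag_max ACF lags compared (default 30).
#' @return List with `cloud` (length `L`), `r_original`, `r_acf`,
#'   `success` (both constraints met), `iterations`.  On failure the best
#'   arrangement found is returned with `success = FALSE`.
#' @export
simulate_cloud <- function(historical_cloud, L, max_corr = 0.1,
                           min_acf_match = 0.998, seed = NULL,
                           max_iter = 20000L, lag_max = 30L) {
  if (length(historical_cloud) < L)
    stop("historical series shorter than requested season", call. = FALSE)
  if (any(historical_cloud < 0 | historical_cloud > 1))
    stop("historical cloud fractions must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  original <- historical_cloud[seq_len(L)]
  vals <- sample(historical_cloud, L, replace = TRUE)
  acf_hist <- acf_vector(historical_cloud, lag_max)

  if (stats::sd(vals) == 0) {
    # degenerate marginal: any arrangement is both decorrelated and
    # ACF-matched by convention
    return(list(cloud = vals, r_original = 0, r_acf = 1, success = TRUE,
                iterations = 0L))
  }

  # initialize by rank-remapping a Gaussian AR surrogate of the historical
  # series so the anneal starts close to the target ACF
  z_hist <- stats::qnorm((rank(historical_cloud) - 0.5) /
                           length(historical_cloud))
  ord_init <- seq_len(L)
  ar_fit <- tryCatch(stats::ar(z_hist, aic = FALSE,
                               order.max = min(10L, L %/% 20L),
                               method = "yule-walker"),
                     error = function(e) NULL)
  if (!is.null(ar_fit) && length(ar_fit$ar)) {
    e <- stats::rnorm(L + 200L, 0, sqrt(ar_fit$var.pred))
    z <- as.numeric(utils::tail(
      stats::filter(e, ar_fit$ar, method = "recursive"), L))
    ord_init <- rank(z, ties.method = "first")
  }
  x <- sort(vals)[ord_init]

  score <- function(x) {
    r_acf <- suppressWarnings(stats::cor(acf_vector(x, lag_max), acf_hist))
    if (!is.finite(r_acf)) r_acf <- -1
    r_orig <- abs(stats::cor(x, original))
    # ACF match is the hard constraint, decorrelation the objective
    pen <- 100 * max(0, min_acf_match - r_acf) + max(0, r_orig - max_corr)
    list(pen = pen, r_acf = r_acf, r_orig = r_orig)
  }
  cur <- score(x)
  best <- list(x = x, sc = cur)
  it <- 0L
  while (cur$pen > 0 && it < max_iter) {
    it <- it + 1L
    ij <- sample.int(L, 2L)
    cand <- x
    cand[ij] <- cand[rev(ij)]
    sc <- score(cand)
    # greedy with occasional sideways moves to escape plateaus
    if (sc$pen < cur$pen ||
        (sc$pen == cur$pen && stats::runif(1) < 0.05)) {
      x <- cand
      cur <- sc
      if (cur$pen < best$sc$pen) best <- list(x = x, sc = cur)
    }
  }
  if (cur$pen > best$sc$pen) {
    x <- best$x
    cur <- best$sc
  }
  list(cloud = x, r_original = stats::cor(x, original), r_acf = cur$r_acf,
       success = cur$pen == 0, iterations = it)
}

#' Offset or stretch a weather season
#'
#' The offset (C) is added to the series' global offset; stretching to a
#' new length resamples the season by linear interpolation of baseline and
#' deviation and nearest-neighbor resampling of cloud cover (cloud
#' fractions are drawn from a distribution; interpolating them would create
#' values never observed).  Deviation variance is not rescaled: the season
#' is a compressed or stretched history, not a re-simulated one.
#'
#' @param w A `weather_series`.
#' @param offset Additional temperature offset (C).
#' @param stretch_to New length in days (in `[2, 366]`), or `NULL` to keep
#'   the length.
#' @return A `weather_series`.
#' @export
transform_season <- function(w, offset = 0, stretch_to = NULL) {
  stopifnot(inherits(w, "weather_series"))
  out <- w
  if (!is.null(stretch_to)) {
    if (stretch_to < 2 || stretch_to > 366)
      stop("`stretch_to` must lie in [2, 366]", call. = FALSE)
    L_old <- nrow(w)
    at <- seq(1, L_old, length.out = stretch_to)
    out <- weather_series(
      t_normal = stats::approx(seq_len(L_old), w$t_normal, at)$y,
      deviation = stats::approx(seq_len(L_old), w$deviation, at)$y,
      cloud = w$cloud[round(at)],
      offset = attr(w, "offset"))
  }
  attr(out, "offset") <- attr(out, "offset") + offset
  out
}

#' Bundle a Boston-like synthetic weather model
#'
#' Packages everything [random_season()] needs to generate random breeding
#' seasons: synthetic climate normals, an AR model fitted to a synthetic
#' "historical" deviation record (an AR(1)-like process with a daily SD of
#' about 3.3 C), and a synthetic historical cloud record (Gaussian-copula
#' AR(1), beta marginal with mean ~0.57).  Real station data can be
#' substituted by building the same list from [read_weather()] output.
#'
#' @param seed Integer seed for the synthetic historical records.
#' @param L Season length of the normals.
#' @param years Years of synthetic history to generate.
#' @param ar_order Order of the fitted deviation model.
#' @return A `weather_model`: `normals` (a `weather_series`), `ar`
#'   (an `ar_model`), `cloud_hist` (historical cloud fractions).
#' @export
boston_weather_model <- function(seed = 1L, L = 214L, years = 10L,
                                 ar_order = 30L) {
  set.seed(derive_seed(seed, 101L))
  n_hist <- years * 365L
  # historical deviations: AR(1) phi = 0.7, stationary SD ~3.3 C
  phi <- 0.7
  innov <- 3.3 * sqrt(1 - phi^2)
  dev_hist <- as.numeric(stats::filter(stats::rnorm(n_hist + 200L, 0, innov),
                                       phi, method = "recursive"))
  dev_hist <- utils::tail(dev_hist, n_hist)
  ar <- fit_ar(dev_hist, order = ar_order)
  # historical clouds: Gaussian-copula AR(1) mapped to a Beta(2, 1.5)
  z <- as.numeric(stats::filter(stats::rnorm(n_hist + 200L), 0.8,
                                method = "recursive"))
  z <- utils::tail(z, n_hist)
  cloud_hist <- stats::qbeta(stats::pnorm(z / stats::sd(z)), 2, 1.5)
  structure(list(normals = synthetic_normals(L = L), ar = ar,
                 cloud_hist = cloud_hist, L = L),
            class = "weather_model")
}

#' Draw one random breeding season from a weather model
#'
#' Baseline normals plus AR-simulated deviations and (optionally) a
#' constrained cloud surrogate; deviation and cloud streams are generated
#' independently, mirroring their lack of correlation in historical data.
#'
#' @param model A `weather_model`.
#' @param seed Integer seed (deviation and cloud streams are derived from
#'   it independently).
#' @param cloud Include a cloud surrogate (`TRUE`) or keep clear skies.
#' @param cloud_iter Swap budget passed to [simulate_cloud()].
#' @return A `weather_series`.
#' @export
random_season <- function(model, seed = 1L, cloud = TRUE,
                          cloud_iter = 5000L) {
  stopifnot(inherits(model, "weather_model"))
  L <- nrow(model$normals)
  dev <- simulate_deviations(model$ar, L, seed = derive_seed(seed, 1L))
  cl <- if (cloud) {
    simulate_cloud(model$cloud_hist, L, seed = derive_seed(seed, 2L),
                   max_iter = cloud_iter)$cloud
  } else 0
  weather_series(model$normals$t_normal, dev, cl,
                 offset = attr(model$normals, "offset"))
}
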