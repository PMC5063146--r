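#' Thermal preference distributions
#'
#' A preference distribution describes the thermal preference index
#' \eqn{p \in [0, 1]} across flies.  The canonical form is a beta
#' distribution; a point mass (zero-variance) form is supported so that
#' degenerate controls (e.g. "all flies identical") can be expressed, and a
#' discrete grid form is used to match the agent model to the
#' difference-equation model bin-for-bin.
#'
#' @param alpha,beta Beta shape parameters, both `> 0`.
#' @return An object of class `pref_dist`.
#' @examples
#' d <- pref_dist(3.8, 8.08)
#' pref_mean(d)
#' @export
pref_dist <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("`alpha` and `beta` must be single positive finite numbers",
         call. = FALSE)
  }
  structure(list(type = "beta", alpha = alpha, beta = beta),
            class = "pref_dist")
}

#' Build a preference distribution from its mean and SD
#'
#' Method-of-moments beta shapes: with mean `m` and variance `v`,
#' `alpha = m (m (1 - m) / v - 1)` and `beta = (1 - m) (m (1 - m) / v - 1)`.
#' An SD of 0 yields a point mass; an SD at or above `sqrt(m (1 - m))` is
#' infeasible for a beta distribution and is rejected.
#'
#' @param mean Mean preference in (0, 1).
#' @param sd Standard deviation of preference, `>= 0`.
#' @return A `pref_dist` (beta, or point mass when `sd = 0`).
#' @examples
#' pref_dist_from_moments(0.32, 0.13)  # the fitted phototactic distribution
#' @export
pref_dist_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0 || mean >= 1)
    stop("`mean` must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stop("`sd` must be a nonnegative number", call. = FALSE)
  if (sd == 0)
    return(structure(list(type = "point", at = mean), class = "pref_dist"))
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop(sprintf(
      "sd = %.4g is infeasible for a beta distribution with mean %.4g (limit %.4g)",
      sd, mean, sqrt(mean * (1 - mean))), call. = FALSE)
  nu <- mean * (1 - mean) / v - 1
  pref_dist(mean * nu, (1 - mean) * nu)
}

#' Fixed (point-mass) preference
#'
#' @param at Preference value in \[0, 1\].
#' @return A point-mass `pref_dist`.
#' @export
pref_point <- function(at) {
  if (!is.numeric(at) || length(at) != 1L || at < 0 || at > 1)
    stop("`at` must be a single value in [0, 1]", call. = FALSE)
  structure(list(type = "point", at = at), class = "pref_dist")
}

#' The study's default preference distribution
#'
#' Beta distribution with mean 0.32 and SD 0.13, the fitted distribution of
#' phototactic preference that parameterizes the life-history model.
#'
#' @return A `pref_dist`.
#' @export
default_pref_dist <- function() pref_dist_from_moments(0.32, 0.13)

#' @rdname pref_dist
#' @param d A `pref_dist`.
#' @export
pref_mean <- function(d) {
  stopifnot(inherits(d, "pref_dist"))
  switch(d$type,
         beta  = d$alpha / (d$alpha + d$beta),
         point = d$at,
         grid  = sum(d$centers * d$weights))
}

#' @rdname pref_dist
#' @export
pref_sd <- function(d) {
  stopifnot(inherits(d, "pref_dist"))
  switch(d$type,
         beta  = {
           s <- d$alpha + d$beta
           sqrt(d$alpha * d$beta / (s^2 * (s + 1)))
         },
         point = 0,
         grid  = {
           m <- sum(d$centers * d$weights)
           sqrt(sum((d$centers - m)^2 * d$weights))
         })
}

#' Draw preference indices
#'
#' @param n Number of draws.
#' @param d A `pref_dist`.
#' @return Numeric vector of length `n` in \[0, 1\].
#' @export
rpref <- function(n, d) {
  stopifnot(inherits(d, "pref_dist"))
  switch(d$type,
         beta  = stats::rbeta(n, d$alpha, d$beta),
         point = rep(d$at, n),
         grid  = sample(d$centers, n, replace = TRUE, prob = d$weights))
}

#' Discretize a preference distribution onto K bins
#'
#' Bin centers are `(k - 0.5)/K` for `k = 1..K`; beta weights are exact bin
#' probabilities, a point mass occupies its nearest bin.  The grid is both
#' the difference-equation model's state space and (via
#' [pref_dist_grid()]) a drawable distribution for matched agent runs.
#'
#' @param d A `pref_dist`.
#' @param K Number of bins (`>= 2`).
#' @return An object of class `pref_grid` with fields `centers`, `weights`.
#' @export
pref_grid <- function(d, K = 101L) {
  stopifnot(inherits(d, "pref_dist"))
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2", call. = FALSE)
  edges <- seq(0, 1, length.out = K + 1L)
  centers <- (edges[-1L] + edges[-(K + 1L)]) / 2
  w <- switch(d$type,
              beta = diff(stats::pbeta(edges, d$alpha, d$beta)),
              point = {
                w <- numeric(K)
                w[min(K, max(1L, findInterval(d$at, edges, rightmost.closed = TRUE)))] <- 1
                w
              },
              grid = {
                w <- numeric(K)
                idx <- pmin(K, pmax(1L, findInterval(d$centers, edges,
                                                     rightmost.closed = TRUE)))
                for (i in seq_along(idx)) w[idx[i]] <- w[idx[i]] + d$weights[i]
                w
              })
  w <- w / sum(w)
  structure(list(centers = centers, weights = w, K = K), class = "pref_grid")
}

#' Preference distribution supported on a grid
#'
#' @param grid A `pref_grid`.
#' @return A `pref_dist` of type `"grid"` drawing bin centers with the grid
#'   weights; used to run the agent model on exactly the state space of the
#'   difference-equation model.
#' @export
pref_dist_grid <- function(grid) {
  stopifnot(inherits(grid, "pref_grid"))
  structure(list(type = "grid", centers = grid$centers,
                 weights = grid$weights), class = "pref_dist")
}

#' @export
print.pref_dist <- function(x, ...) {
  switch(x$type,
         beta = cat(sprintf(
           "Preference distribution: Beta(%.4g, %.4g)  mean %.3f  sd %.3f\n",
           x$alpha, x$beta, pref_mean(x), pref_sd(x))),
         point = cat(sprintf("Preference distribution: point mass at %.3f\n",
                             x$at)),
         grid = cat(sprintf(
           "Preference distribution: %d-point grid  mean %.3f  sd %.3f\n",
           length(x$centers), pref_mean(x), pref_sd(x))))
  invisible(x)
}

# Derive a child seed from a root seed and a stream index; kept below 2^31
# so it is always a valid R integer seed.
derive_seed <- function(root, stream) {
  as.integer((as.double(root) * 48271 + as.double(stream) * 16807) %%
               2147483647) + 1L
}
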