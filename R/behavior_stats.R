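# Statistics of behavioral individuality: trial filters, preference
# indices, overdispersion tests against the binomial null, beta-binomial
# fits, variance partitions, persistence, sequential mutual information,
# and the selection-based heritability estimator.

longest_true_run <- function(x) {
  r <- rle(x)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Filter flies by trial count and immobility
#'
#' Flies with fewer than `min_choices` non-missing trials yield noisy
#' preference estimates and are removed; flies that did not move for
#' `max_immobile_run` or more successive trials are removed because such
#' trials are not independent choices.  Immobility is taken from the
#' matrix's `immobile` indicator attribute when present (set by the
#' generator's injection flag); for position matrices, runs of exactly
#' identical successive non-missing values are additionally detected.
#'
#' @param m A `choice_matrix` or `position_matrix`.
#' @param min_choices Minimum non-missing trials to retain a fly
#'   (default 10).
#' @param max_immobile_run Immobility run length triggering removal
#'   (default 3).
#' @return A list with `matrix` (the retained flies) and `discarded`
#'   (data frame of fly id and reason).  A warning is raised if no fly
#'   survives.
#' @export
filter_flies <- function(m, min_choices = 10L, max_immobile_run = 3L) {
  stopifnot(inherits(m, "behavior_matrix"))
  if (min_choices < 1L || max_immobile_run < 1L)
    stop("thresholds must be at least 1", call. = FALSE)
  valid <- rowSums(!is.na(m))
  too_few <- valid < min_choices

  imm_attr <- attr(m, "immobile")
  immobile <- rep(FALSE, nrow(m))
  if (!is.null(imm_attr))
    immobile <- apply(imm_attr, 1L, longest_true_run) >= max_immobile_run
  if (inherits(m, "position_matrix")) {
    same_as_prev <- function(x) {
      ok <- !is.na(x)
      rep_run <- ok[-1L] & ok[-length(x)] & x[-1L] == x[-length(x)]
      # a run of k identical repeats means k+1 identical trials
      longest_true_run(rep_run) + 1L
    }
    immobile <- immobile | apply(m, 1L, same_as_prev) >= max_immobile_run
  }

  reason <- ifelse(too_few, "too_few_choices",
                   ifelse(immobile, "immobile_run", NA_character_))
  drop <- !is.na(reason)
  discarded <- data.frame(fly_id = rownames(m)[drop],
                          reason = reason[drop], stringsAsFactors = FALSE)
  kept <- m[!drop, , drop = FALSE]
  for (a in c("n_trials", "bounds"))
    attr(kept, a) <- attr(m, a)
  if (!is.null(imm_attr))
    attr(kept, "immobile") <- imm_attr[!drop, , drop = FALSE]
  class(kept) <- class(m)
  if (nrow(kept) == 0L)
    warning("no flies survive filtering", call. = FALSE)
  list(matrix = kept, discarded = discarded)
}

#' Per-fly preference indices
#'
#' Binary matrices yield the fraction of light choices among non-missing
#' trials; position matrices yield the mean resting temperature (C).
#'
#' @param m A `choice_matrix` or `position_matrix` (already filtered).
#' @return Named numeric vector, one entry per fly with at least one valid
#'   trial; flies without valid trials are dropped with a warning.
#' @export
preference_indices <- function(m) {
  stopifnot(inherits(m, "behavior_matrix"))
  idx <- rowMeans(m, na.rm = TRUE)
  bad <- is.nan(idx)
  if (any(bad)) {
    warning(sprintf("%d flies with no valid trials excluded", sum(bad)),
            call. = FALSE)
    idx <- idx[!bad]
  }
  idx
}

# Monte-Carlo machinery shared by the overdispersion tests.  For a vector of
# per-fly light counts with per-fly valid trial counts `nn`, simulates
# `n_null` parametric-bootstrap datasets from the binomial null (pooled p
# re-estimated within each simulated dataset, so observed and simulated
# statistics are exchangeable under the null) and returns the KS and
# variance-bootstrap p-values.
binomial_null_mc <- function(k, nn, n_null) {
  N <- length(k)
  phat <- sum(k) / sum(nn)
  frac_obs <- k / nn
  v_obs <- stats::var(frac_obs)

  uniform_n <- length(unique(nn)) == 1L
  n1 <- nn[1L]

  # simulated counts: N x n_null
  sim <- matrix(stats::rbinom(N * n_null, rep(nn, n_null), phat),
                nrow = N, ncol = n_null)
  phat_sim <- colSums(sim) / sum(nn)
  frac_sim <- sim / nn
  v_sim <- (colSums(frac_sim^2) - colSums(frac_sim)^2 / N) / (N - 1)
  boot_p <- (1 + sum(v_sim >= v_obs)) / (1 + n_null)

  ks_stat_fraction <- function(fr, p, nvec) {
    # sup |ECDF - F0| over the support of per-fly fractions, F0 the mixture
    # of per-fly binomial CDFs
    grid <- sort(unique(fr))
    ec <- stats::ecdf(fr)(grid)
    F0 <- vapply(grid, function(g)
      mean(stats::pbinom(floor(g * nvec + 1e-9), nvec, p)), numeric(1))
    max(abs(ec - F0))
  }

  if (uniform_n) {
    supp <- 0:n1
    F0_obs <- stats::pbinom(supp, n1, phat)
    ec_obs <- vapply(supp, function(s) mean(k <= s), numeric(1))
    d_obs <- max(abs(ec_obs - F0_obs))
    # vectorized over simulations: ECDF and null CDF per support point
    d_sim <- numeric(n_null)
    F0_sim <- outer(supp, phat_sim, function(s, p) stats::pbinom(s, n1, p))
    for (si in seq_along(supp)) {
      dev <- abs(colMeans(sim <= supp[si]) - F0_sim[si, ])
      d_sim <- pmax(d_sim, dev)
    }
  } else {
    d_obs <- ks_stat_fraction(frac_obs, phat, nn)
    d_sim <- vapply(seq_len(n_null), function(j)
      ks_stat_fraction(frac_sim[, j], phat_sim[j], nn), numeric(1))
  }
  ks_p <- (1 + sum(d_sim >= d_obs)) / (1 + n_null)
  list(ks_stat = d_obs, ks_p = ks_p, boot_p = boot_p,
       obs_var = v_obs, phat = phat)
}

#' Overdispersion of per-fly choice counts against the binomial null
#'
#' Tests whether flies choose the light with identical probabilities.  Under
#' the null, per-fly light counts are binomial(valid trials, pooled p).
#' Three tests are returned: (i) a one-sample KS test of the count
#' distribution against the binomial expectation, with the p-value obtained
#' by parametric-bootstrap Monte Carlo (the asymptotic KS distribution is
#' anti-conservative on discrete counts); (ii) a chi-square test of variance
#' comparing the observed variance of per-fly fractions to the binomial
#' sampling variance (upper tail); (iii) a bootstrap test, the fraction of
#' null datasets whose between-fly variance reaches the observed one.
#'
#' @param m A filtered `choice_matrix` with at least 2 flies.
#' @param n_boot Number of Monte-Carlo null datasets (values below 100 give
#'   unstable p-values and raise a warning).
#' @param seed Integer seed for the Monte Carlo.
#' @return An `overdispersion_report`: `pooled_p`, `obs_sd`, `null_sd`,
#'   `ks_stat`, `ks_p`, `chi2_stat`, `chi2_df`, `chi2_p`, `bootstrap_p`,
#'   `n_flies`, `n_trials`.
#' @export
overdispersion_test <- function(m, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(m, "choice_matrix"))
  if (n_boot < 100L)
    warning("n_boot < 100 gives unstable Monte-Carlo p-values",
            call. = FALSE)
  k <- rowSums(m == 1L, na.rm = TRUE)
  nn <- rowSums(!is.na(m))
  keep <- nn > 0L
  k <- k[keep]; nn <- nn[keep]
  if (length(k) < 2L)
    stop("overdispersion tests require at least 2 flies", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  mc <- binomial_null_mc(k, nn, n_boot)
  phat <- mc$phat
  # chi-square test of variance on the fraction scale; null variance is the
  # mean binomial sampling variance of a per-fly fraction
  null_var <- mean(phat * (1 - phat) / nn)
  N <- length(k)
  chi2_stat <- (N - 1) * mc$obs_var / null_var
  chi2_p <- stats::pchisq(chi2_stat, df = N - 1, lower.tail = FALSE)

  n_trials <- attr(m, "n_trials")
  structure(list(pooled_p = phat,
                 obs_sd = sqrt(mc$obs_var),
                 null_sd = sqrt(phat * (1 - phat) / n_trials),
                 ks_stat = mc$ks_stat, ks_p = mc$ks_p,
                 chi2_stat = chi2_stat, chi2_df = N - 1, chi2_p = chi2_p,
                 bootstrap_p = mc$boot_p,
                 n_flies = N, n_trials = n_trials, n_boot = n_boot),
            class = "overdispersion_report")
}

#' @export
print.overdispersion_report <- function(x, ...) {
  cat(sprintf("Overdispersion vs binomial null (%d flies, %d trials)\n",
              x$n_flies, x$n_trials))
  cat(sprintf("  pooled p = %.3f   obs SD = %.4f   null SD = %.4f\n",
              x$pooled_p, x$obs_sd, x$null_sd))
  cat(sprintf("  KS: D = %.4f, p = %.3g (Monte Carlo, %d null sets)\n",
              x$ks_stat, x$ks_p, x$n_boot))
  cat(sprintf("  chi-square variance: X2 = %.1f, df = %d, p = %.3g\n",
              x$chi2_stat, x$chi2_df, x$chi2_p))
  cat(sprintf("  bootstrap variance: p = %.3g\n", x$bootstrap_p))
  invisible(x)
}

#' Maximum-likelihood beta-binomial fit to per-fly light counts
#'
#' Fits shapes (alpha, beta) by numerical maximization of the beta-binomial
#' likelihood; the binomial model is the boundary case alpha + beta -> Inf
#' at fixed mean, so the fitted log-likelihood is never below the binomial
#' one.  Fits whose precision `alpha + beta` reaches the internal cap are
#' flagged `near_binomial` (no evidence of overdispersion); all-equal counts
#' are flagged `degenerate`.
#'
#' @param counts Per-fly light counts in `0..n`.
#' @param n Trials per fly (single value).
#' @param cap Upper bound on `alpha + beta` before the fit is declared
#'   binomial-like.
#' @return List with `dist` (a [pref_dist]), `loglik`, `loglik_binomial`,
#'   `converged`, `near_binomial`, `degenerate`.
#' @export
fit_beta_binomial <- function(counts, n, cap = 1e6) {
  if (any(counts < 0 | counts > n))
    stop("counts must lie in [0, n]", call. = FALSE)
  N <- length(counts)
  phat <- sum(counts) / (N * n)
  ll_binom <- sum(stats::dbinom(counts, n, phat, log = TRUE))
  if (length(unique(counts)) == 1L) {
    warning("all counts identical: beta-binomial fit is degenerate",
            call. = FALSE)
    return(list(dist = NULL, loglik = ll_binom, loglik_binomial = ll_binom,
                converged = FALSE, near_binomial = FALSE, degenerate = TRUE))
  }
  nll <- function(theta) {
    a <- exp(theta[1]); b <- exp(theta[2])
    -sum(lchoose(n, counts) + lbeta(counts + a, n - counts + b) - lbeta(a, b))
  }
  # start at method of moments (floored dispersion so the start is interior)
  v <- max(stats::var(counts / n) - phat * (1 - phat) / n,
           phat * (1 - phat) / 100)
  nu <- max(phat * (1 - phat) / v - 1, 0.5)
  fit <- stats::optim(log(c(phat * nu, (1 - phat) * nu)), nll,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  near_binomial <- (a + b) > cap
  if (near_binomial) {
    s <- cap
    a <- phat * s; b <- (1 - phat) * s
  }
  list(dist = pref_dist(a, b), loglik = -fit$value,
       loglik_binomial = ll_binom,
       converged = fit$convergence == 0L,
       near_binomial = near_binomial, degenerate = FALSE)
}

percentile_ci <- function(x, level = 0.95) {
  stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                  names = FALSE)
}

#' Partition variance of binary choice fractions into individual and
#' sampling components
#'
#' The observed variance of per-fly light fractions is the sum of true
#' between-fly variance and binomial sampling noise.  The between component
#' is `max(0, var(fractions) - mean(phat_i (1 - phat_i) / (n_i - 1)))`
#' (the subtrahend is the unbiased within-fly sampling variance); its square
#' root is the preference-index SD across individuals.
#'
#' @param m A filtered `choice_matrix`.
#' @param n_boot Bootstrap draws (flies resampled) for the percentile CI.
#' @param seed Integer seed.
#' @return A `variance_partition`: `frac_individual`, `sd_individual`,
#'   `ci` (95% percentile CI on `sd_individual`), `obs_var`, `n_flies`.
#' @export
variance_partition_binary <- function(m, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(m, "choice_matrix"))
  if (!is.null(seed)) set.seed(seed)
  k <- rowSums(m == 1L, na.rm = TRUE)
  nn <- rowSums(!is.na(m))
  keep <- nn > 1L
  k <- k[keep]; nn <- nn[keep]
  part <- function(k, nn) {
    f <- k / nn
    vtot <- stats::var(f)
    within <- mean(f * (1 - f) / (nn - 1))
    between <- max(0, vtot - within)
    c(frac = if (vtot > 0) between / vtot else 0,
      sd = sqrt(between), vtot = vtot)
  }
  est <- part(k, nn)
  boot <- replicate(n_boot, {
    i <- sample.int(length(k), replace = TRUE)
    part(k[i], nn[i])["sd"]
  })
  structure(list(frac_individual = unname(est["frac"]),
                 sd_individual = unname(est["sd"]),
                 ci = percentile_ci(boot),
                 obs_var = unname(est["vtot"]),
                 n_flies = length(k)),
            class = "variance_partition")
}

#' Partition variance of continuous gradient positions with one-way ANOVA
#'
#' One-way fixed-effects ANOVA on fly identity; variance components by the
#' mean-squares method with the unbalanced-design correction
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`: between = `(MSB - MSW)/n0`
#' (truncated at 0), fraction = between / (between + within).
#'
#' @param m A filtered `position_matrix` with `>= 2` flies, each with
#'   `>= 2` trials.
#' @param n_boot,seed Bootstrap (over flies) settings for the CI on
#'   `sd_individual`.
#' @return A `variance_partition` with an additional `anova` element
#'   (`F`, `df1`, `df2`, `p`).
#' @export
variance_partition_continuous <- function(m, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(m, "position_matrix"))
  if (!is.null(seed)) set.seed(seed)
  long <- data.frame(fly = rep(rownames(m), ncol(m)), value = as.vector(m))
  long <- long[!is.na(long$value), ]
  n_i <- table(long$fly)
  if (length(n_i) < 2L) stop("need at least 2 flies", call. = FALSE)
  if (any(n_i < 2L))
    stop("every fly needs at least 2 valid trials", call. = FALSE)

  components <- function(long) {
    n_i <- table(long$fly)
    a <- length(n_i); N <- nrow(long)
    if (stats::var(long$value) == 0)
      return(list(frac = 0, sd = 0, F = NA_real_, df1 = a - 1, df2 = N - a,
                  p = NA_real_, flagged = TRUE))
    av <- stats::aov(value ~ fly, data = long)
    tab <- summary(av)[[1]]
    msb <- tab["fly", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    n0 <- (N - sum(n_i^2) / N) / (a - 1)
    between <- max(0, (msb - msw) / n0)
    list(frac = between / (between + msw), sd = sqrt(between),
         F = tab["fly", "F value"], df1 = a - 1, df2 = N - a,
         p = tab["fly", "Pr(>F)"], flagged = FALSE)
  }
  est <- components(long)
  flies <- names(n_i)
  boot <- replicate(n_boot, {
    pick <- sample(flies, replace = TRUE)
    bl <- do.call(rbind, lapply(seq_along(pick), function(j) {
      d <- long[long$fly == pick[j], ]
      d$fly <- paste0("b", j)
      d
    }))
    components(bl)$sd
  })
  structure(list(frac_individual = est$frac, sd_individual = est$sd,
                 ci = percentile_ci(boot),
                 anova = list(F = est$F, df1 = est$df1, df2 = est$df2,
                              p = est$p, flagged = est$flagged),
                 n_flies = length(n_i)),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(
    "Variance partition (%d flies): %.1f%% between individuals, SD = %.4g (95%% CI %.4g-%.4g)\n",
    x$n_flies, 100 * x$frac_individual, x$sd_individual, x$ci[1], x$ci[2]))
  if (!is.null(x$anova) && !x$anova$flagged)
    cat(sprintf("  one-way ANOVA: F = %.3g, df = (%d, %d), p = %.3g\n",
                x$anova$F, x$anova$df1, x$anova$df2, x$anova$p))
  invisible(x)
}

#' Day-to-day persistence of individual preference
#'
#' Pearson correlation between per-fly indices measured on two days; pairs
#' with a missing day are dropped.
#'
#' @param day1,day2 Named per-fly index vectors (matched by name when both
#'   are named, by position otherwise).
#' @return List with `r`, `p` (two-sided), `df` (`n - 2`), `n`.
#' @export
persistence_correlation <- function(day1, day2) {
  if (!is.null(names(day1)) && !is.null(names(day2))) {
    ids <- intersect(names(day1), names(day2))
    day1 <- day1[ids]; day2 <- day2[ids]
  } else if (length(day1) != length(day2)) {
    stop("unnamed vectors must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(day1, day2)
  x <- day1[ok]; y <- day2[ok]
  if (length(x) < 3L)
    stop("persistence correlation requires at least 3 complete pairs",
         call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}

plugin_mi <- function(x0, x1) {
  # plug-in mutual information (bits) of paired binary sequences with the
  # 0 log 0 = 0 convention
  tab <- table(factor(x0, levels = 0:1), factor(x1, levels = 0:1))
  pj <- tab / sum(tab)
  px <- rowSums(pj); py <- colSums(pj)
  terms <- pj * log2(pj / outer(px, py))
  sum(terms[pj > 0])
}

#' Mean sequential mutual information of choices
#'
#' For each fly, the plug-in mutual information (bits) between successive
#' non-missing choices; the mean across flies quantifies trial-to-trial
#' dependence (0 = independent choices).  Plug-in MI has a positive
#' small-sample bias, so a jackknife (over successive pairs) bias estimate
#' is reported alongside.
#'
#' @param m A `choice_matrix`; flies with fewer than 2 successive valid
#'   pairs are excluded.
#' @return List with `mi_mean`, `bias_mean` (mean jackknife bias),
#'   `mi_per_fly`, `n_flies`.
#' @export
sequential_mutual_information <- function(m) {
  stopifnot(inherits(m, "choice_matrix"))
  per_fly <- apply(m, 1L, function(x) {
    ok <- !is.na(x[-length(x)]) & !is.na(x[-1L])
    x0 <- x[-length(x)][ok]; x1 <- x[-1L][ok]
    np <- length(x0)
    if (np < 2L) return(c(NA_real_, NA_real_))
    mi <- plugin_mi(x0, x1)
    loo <- vapply(seq_len(np), function(i) plugin_mi(x0[-i], x1[-i]),
                  numeric(1))
    c(mi, (np - 1) * (mean(loo) - mi))
  })
  mi <- per_fly[1L, ]
  keep <- !is.na(mi)
  if (!any(keep)) stop("no fly has 2 or more successive valid pairs",
                       call. = FALSE)
  list(mi_mean = mean(mi[keep]),
       bias_mean = mean(per_fly[2L, keep]),
       mi_per_fly = mi[keep], n_flies = sum(keep))
}

#' Selection estimator of heritability (h2 = R/S)
#'
#' Selection differential `S` is the midparent deviation of the selected
#' parents from the population mean; response `R` is the progeny-mean
#' deviation.  Rather than averaging the two per-arm ratios (unstable when
#' one arm's `S` is small), the two arms are combined by a single regression
#' of brood means on midparent scores through the population mean:
#' `h2 = sum((m_i - mu)(b_i - mu)) / sum((m_i - mu)^2)`.  The SE and CI are
#' obtained by bootstrap over crosses.
#'
#' @param cross A `cross_dataset` with both selection arms present.
#' @param n_boot,seed Bootstrap settings.
#' @param s_tol Minimum root-mean-square midparent deviation; below it the
#'   estimator is undefined and an error is raised.
#' @return A `heritability_estimate`: `h2`, `se`, `ci`, and per-arm `S`,
#'   `R` in `arms`.
#' @export
heritability_fisher <- function(cross, n_boot = 1000L, seed = NULL,
                                s_tol = 1e-3) {
  stopifnot(inherits(cross, "cross_dataset"))
  if (!all(c("shade", "light") %in% cross$parent_scores$arm))
    stop("both selection arms must be present", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- mean(preference_indices(cross$population))
  mid <- cross$parent_scores$midparent
  bmeans <- vapply(cross$broods,
                   function(b) mean(preference_indices(b)), numeric(1))
  bmeans <- bmeans[cross$parent_scores$cross]
  if (sqrt(mean((mid - mu)^2)) < s_tol)
    stop("selection differential below tolerance: h2 = R/S undefined",
         call. = FALSE)
  h2_of <- function(i) sum((mid[i] - mu) * (bmeans[i] - mu)) /
    sum((mid[i] - mu)^2)
  h2 <- h2_of(seq_along(mid))
  boot <- replicate(n_boot, h2_of(sample.int(length(mid), replace = TRUE)))
  arms <- do.call(rbind, lapply(c("shade", "light"), function(a) {
    i <- cross$parent_scores$arm == a
    data.frame(arm = a, S = mean(mid[i]) - mu, R = mean(bmeans[i]) - mu)
  }))
  structure(list(h2 = h2, se = stats::sd(boot), ci = percentile_ci(boot),
                 arms = arms, population_mean = mu),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("Selection heritability h2 = R/S: %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$h2, x$se, x$ci[1], x$ci[2]))
  for (i in seq_len(nrow(x$arms)))
    cat(sprintf("  %s arm: S = %+.3f, R = %+.3f\n",
                x$arms$arm[i], x$arms$S[i], x$arms$R[i]))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of preference distributions
#'
#' Wraps the standard two-sample KS test.  Preference indices are discrete
#' (fractions of a fixed trial count), so ties occur; the asymptotic
#' statistic is used (`exact = FALSE`) and the tie warning is suppressed,
#' which is the usual convention for count-derived indices.
#'
#' @param a,b Nonempty numeric vectors of per-fly indices.
#' @return List with `statistic` and `p`.
#' @export
compare_distributions <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be nonempty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
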