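# Estimators and tests for behavioral individuality.

test_that("trial filter removes sparse and immobile flies with reasons", {
  m <- gen_choice_matrix(6, 24, dist = 0.4, seed = 1,
                         immobile_flies = 3L, immobile_run = 3L)
  m[1, 1:15] <- NA  # 9 valid trials of 24
  out <- filter_flies(m)
  expect_setequal(out$discarded$fly_id, c("fly_1", "fly_3"))
  expect_equal(out$discarded$reason[out$discarded$fly_id == "fly_1"],
               "too_few_choices")
  expect_equal(out$discarded$reason[out$discarded$fly_id == "fly_3"],
               "immobile_run")
  # retained flies are unchanged
  expect_identical(unclass(out$matrix)["fly_2", ], unclass(m)["fly_2", ])

  # position matrices: identical successive values are themselves the
  # no-movement signature
  pm <- gen_position_matrix(4, 10, seed = 2)
  pm[2, 4:6] <- 22.5
  outp <- filter_flies(pm)
  expect_true("fly_2" %in% outp$discarded$fly_id)

  sparse <- gen_choice_matrix(1, 24, dist = 0.4, seed = 9)
  sparse[1, 1:15] <- NA
  expect_warning(filter_flies(sparse), "no flies")
})

test_that("preference indices are per-fly means over valid trials", {
  m <- gen_choice_matrix(2, 4, dist = 0.5, seed = 1)
  m[1, ] <- c(1, 1, 0, 0)
  m[2, ] <- c(1, 1, 1, 1)
  expect_equal(unname(preference_indices(m)), c(0.5, 1.0))

  pm <- gen_position_matrix(1, 2, seed = 1)
  pm[1, ] <- c(20, 26)
  expect_equal(unname(preference_indices(pm)), 23)

  m[2, ] <- NA
  expect_warning(idx <- preference_indices(m), "no valid trials")
  expect_equal(length(idx), 1L)
})

test_that("overdispersion tests reject heterogeneous flies, not null flies", {
  # beta-distributed preferences, the observed phototaxis design
  m <- gen_choice_matrix(219, 24, default_pref_dist(), seed = 2)
  od <- overdispersion_test(m, n_boot = 1000, seed = 3)
  expect_lt(od$ks_p, 0.01)
  expect_lt(od$chi2_p, 1e-6)
  expect_lt(od$bootstrap_p, 0.01)
  expect_gt(od$obs_sd, od$null_sd)
  expect_equal(od$null_sd,
               sqrt(od$pooled_p * (1 - od$pooled_p) / 24), tolerance = 1e-12)

  # identical choice probabilities: no rejection expected at alpha 0.01
  m0 <- gen_choice_matrix(219, 24, dist = 0.32, seed = 4)
  od0 <- overdispersion_test(m0, n_boot = 500, seed = 5)
  expect_gt(od0$ks_p, 0.01)
  expect_gt(od0$chi2_p, 0.01)
  expect_gt(od0$bootstrap_p, 0.01)

  expect_error(overdispersion_test(gen_choice_matrix(1, 24, seed = 1)),
               "at least 2 flies")
  expect_warning(overdispersion_test(m0, n_boot = 50, seed = 1),
                 "unstable")
})

test_that("overdispersion machinery handles unequal valid trial counts", {
  m <- gen_choice_matrix(80, 24, default_pref_dist(), seed = 6,
                         missing_rate = 0.15)
  od <- overdispersion_test(m, n_boot = 300, seed = 7)
  expect_true(all(c(od$ks_p, od$chi2_p, od$bootstrap_p) >= 0 &
                    c(od$ks_p, od$chi2_p, od$bootstrap_p) <= 1))
  expect_lt(od$chi2_p, 0.01)
})

test_that("beta-binomial fit recovers shapes and flags boundary cases", {
  k <- rowSums(gen_choice_matrix(10000, 24, pref_dist(3.8, 8.08),
                                 seed = 6) == 1)
  fit <- fit_beta_binomial(k, 24)
  expect_true(fit$converged)
  expect_false(fit$near_binomial)
  expect_equal(fit$dist$alpha, 3.8, tolerance = 0.1 * 3.8)
  expect_equal(fit$dist$beta, 8.08, tolerance = 0.1 * 8.08)
  expect_gte(fit$loglik, fit$loglik_binomial)

  set.seed(3)
  fit0 <- fit_beta_binomial(rbinom(5000, 24, 0.32), 24)
  expect_true(fit0$near_binomial)
  expect_gte(fit0$loglik, fit0$loglik_binomial - 1e-6)

  expect_warning(fitd <- fit_beta_binomial(rep(24L, 10), 24), "degenerate")
  expect_true(fitd$degenerate)
  expect_error(fit_beta_binomial(c(1, 25), 24), "counts")
})

test_that("binary variance partition separates signal from sampling noise", {
  # null: all heterogeneity is binomial noise
  m0 <- gen_choice_matrix(219, 24, dist = 0.32, seed = 8)
  v0 <- variance_partition_binary(m0, n_boot = 200, seed = 1)
  expect_lt(v0$sd_individual, 0.03)
  # maximal separation
  m2 <- gen_choice_matrix(2, 24, dist = 0.5, seed = 1)
  m2[1, ] <- 0; m2[2, ] <- 1
  v2 <- variance_partition_binary(m2, n_boot = 100, seed = 1)
  expect_gt(v2$frac_individual, 0.9)
})

test_that("continuous variance partition matches ANOVA logic", {
  pm <- gen_position_matrix(2, 40, between_sd = 0, within_sd = 0.01,
                            seed = 9)
  pm[1, ] <- 20 + unclass(pm)[1, ] - mean(unclass(pm)[1, ])
  pm[2, ] <- 26 + unclass(pm)[2, ] - mean(unclass(pm)[2, ])
  v <- variance_partition_continuous(pm, n_boot = 100, seed = 1)
  expect_gt(v$frac_individual, 0.99)
  expect_gt(v$anova$F, 100)

  # all-identical values: flagged, zero fraction
  pc <- gen_position_matrix(3, 5, between_sd = 0, within_sd = 0, seed = 1)
  vc <- variance_partition_continuous(pc, n_boot = 50, seed = 1)
  expect_true(vc$anova$flagged)
  expect_equal(vc$frac_individual, 0)

  one_trial <- gen_position_matrix(3, 1, seed = 1)
  expect_error(variance_partition_continuous(one_trial), "at least 2")
})

test_that("variance partitions are invariant to fly and trial order", {
  m <- gen_choice_matrix(50, 24, default_pref_dist(), seed = 10)
  v1 <- variance_partition_binary(m, n_boot = 50, seed = 1)
  perm <- m[sample(nrow(m)), , drop = FALSE]
  class(perm) <- class(m); attr(perm, "n_trials") <- 24
  v2 <- variance_partition_binary(perm, n_boot = 50, seed = 1)
  expect_equal(v1$sd_individual, v2$sd_individual, tolerance = 1e-12)

  pm <- gen_position_matrix(20, 10, seed = 11)
  w1 <- variance_partition_continuous(pm, n_boot = 20, seed = 1)
  pm2 <- pm
  for (i in seq_len(nrow(pm2))) pm2[i, ] <- pm2[i, sample(ncol(pm2))]
  w2 <- variance_partition_continuous(pm2, n_boot = 20, seed = 1)
  expect_equal(w1$sd_individual, w2$sd_individual, tolerance = 1e-12)
  expect_equal(w1$anova$F, w2$anova$F, tolerance = 1e-12)
})

test_that("persistence correlation behaves at the identity and null", {
  x <- runif(30)
  expect_equal(persistence_correlation(x, x)$r, 1)
  set.seed(12)
  r0 <- persistence_correlation(rnorm(2000), rnorm(2000))
  expect_lt(abs(r0$r), 0.1)
  expect_equal(r0$df, 1998)
  expect_error(persistence_correlation(1:2, 1:2), "at least 3")
})

test_that("retest correlation is attenuated by binomial sampling noise", {
  # same per-fly p scored on two days: E[r] ~ reliability of a 24-trial
  # score, about 0.67 for the fitted preference distribution
  set.seed(13)
  rs <- replicate(8, {
    p <- rpref(72, default_pref_dist())
    d1 <- rbinom(72, 24, p) / 24
    d2 <- rbinom(72, 24, p) / 24
    persistence_correlation(d1, d2)$r
  })
  expect_gt(mean(rs), 0.60)
  expect_lt(mean(rs), 0.75)
})

test_that("sequential mutual information captures dependence in bits", {
  # 25 trials give 24 successive pairs with exactly uniform marginals
  m <- gen_choice_matrix(1, 25, dist = 0.5, seed = 1)
  m[1, ] <- rep_len(c(0, 1), 25)
  expect_equal(sequential_mutual_information(m)$mi_mean, 1)
  m[1, ] <- 1
  expect_equal(sequential_mutual_information(m)$mi_mean, 0)
  # iid choices: small positive plug-in bias only
  mi <- sequential_mutual_information(
    gen_choice_matrix(219, 24, dist = 0.32, seed = 14))
  expect_gt(mi$mi_mean, 0)
  expect_lt(mi$mi_mean, 0.08)
  expect_gt(mi$bias_mean, 0)
})

test_that("selection heritability estimator recovers the truth", {
  cd <- gen_cross_dataset(1, 15, 40, pop_size = 400, seed = 15)
  he <- heritability_fisher(cd, n_boot = 300, seed = 1)
  expect_equal(he$h2, 1, tolerance = 0.1)
  expect_lt(he$arms$S[he$arms$arm == "shade"], 0)
  expect_gt(he$arms$S[he$arms$arm == "light"], 0)

  cd0 <- gen_cross_dataset(0, 15, 40, pop_size = 400, seed = 16)
  he0 <- heritability_fisher(cd0, n_boot = 300, seed = 1)
  expect_lt(abs(he0$h2), 3 * he0$se + 0.05)
})

test_that("distribution comparison uses the two-sample KS convention", {
  a <- rpref(200, default_pref_dist())
  expect_equal(compare_distributions(a, a)$statistic, 0)
  expect_equal(compare_distributions(a, a)$p, 1)
  set.seed(17)
  b <- pmin(rpref(200, default_pref_dist()) + 0.3, 1)
  expect_lt(compare_distributions(a, b)$p, 0.01)
  expect_no_error(compare_distributions(c(0.1, 0.5, 0.9), c(0.2, 0.5, 0.7)))
  expect_error(compare_distributions(numeric(0), a), "nonempty")
})
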