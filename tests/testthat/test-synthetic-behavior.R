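# Generators for synthetic behavioral data.

test_that("choice matrices honor fixed probabilities and seeds", {
  m0 <- gen_choice_matrix(5, 24, dist = 0, seed = 1)
  expect_true(all(m0 == 0))
  m1 <- gen_choice_matrix(3, 10, dist = 1, seed = 1)
  expect_true(all(m1 == 1))

  a <- gen_choice_matrix(40, 24, seed = 42)
  b <- gen_choice_matrix(40, 24, seed = 42)
  expect_identical(unclass(a), unclass(b))
})

test_that("method-of-moments beta shapes match the target moments", {
  d <- pref_dist_from_moments(0.32, 0.13)
  expect_equal(d$alpha, 3.80, tolerance = 0.01)
  expect_equal(d$beta, 8.08, tolerance = 0.01)
  expect_equal(pref_mean(d), 0.32, tolerance = 1e-12)
  expect_equal(pref_sd(d), 0.13, tolerance = 1e-12)
  expect_error(pref_dist_from_moments(0.32, 0.5), "infeasible")
  expect_equal(pref_sd(pref_dist_from_moments(0.32, 0)), 0)
})

test_that("per-fly light fractions have the expected spread", {
  # beta-distributed preferences: sample mean of fractions near dist mean
  m <- gen_choice_matrix(10000, 24, default_pref_dist(), seed = 7)
  f <- rowMeans(m)
  expect_equal(mean(f), 0.32, tolerance = 0.01)
  # fixed p: spread is pure binomial sampling noise, sqrt(p(1-p)/24)
  mf <- gen_choice_matrix(10000, 24, dist = 0.32, seed = 8)
  expect_lt(abs(sd(rowMeans(mf)) - sqrt(0.32 * 0.68 / 24)), 0.003)
})

test_that("missingness injection leaves non-missing values untouched", {
  full <- gen_choice_matrix(60, 24, seed = 11, missing_rate = 0)
  holey <- gen_choice_matrix(60, 24, seed = 11, missing_rate = 0.2)
  keep <- !is.na(holey)
  expect_gt(sum(!keep), 0)
  expect_identical(unclass(holey)[keep], unclass(full)[keep])
})

test_that("position matrices collapse to the grand mean without variance", {
  m <- gen_position_matrix(4, 6, grand_mean = 23.1, between_sd = 0,
                           within_sd = 0, seed = 1)
  expect_true(all(m == 23.1))
  expect_error(gen_position_matrix(4, 6, bounds = c(30, 18)), "ordered")
})

test_that("position matrices stay in bounds and reproduce the 14.7% fraction", {
  m <- gen_position_matrix(2000, 20, seed = 5)
  expect_true(all(m >= 18 & m <= 30))
  # intraclass fraction implied by between_sd 1.4, within_sd 3.37
  v_between <- var(rowMeans(m)) - mean(apply(m, 1, var)) / 20
  frac <- v_between / (v_between + mean(apply(m, 1, var)))
  # clipping at the arena walls shaves a little variance, so the band is
  # absolute rather than tight-relative
  expect_lt(abs(frac - 0.147), 0.015)
  expect_identical(unclass(gen_position_matrix(10, 20, seed = 3)),
                   unclass(gen_position_matrix(10, 20, seed = 3)))
})

test_that("cross datasets inherit as configured", {
  # no heritability: broods center on the population mean in both arms
  cd0 <- gen_cross_dataset(0, 10, 60, pop_size = 300, seed = 21)
  bm <- vapply(cd0$broods, function(b) mean(rowMeans(b)), numeric(1))
  expect_equal(mean(bm[cd0$parent_scores$arm == "shade"]), 0.32,
               tolerance = 0.03)
  expect_equal(mean(bm[cd0$parent_scores$arm == "light"]), 0.32,
               tolerance = 0.03)
  # full heritability: each brood centers on its midparent
  cd1 <- gen_cross_dataset(1, 10, 60, pop_size = 300, seed = 22)
  bm1 <- vapply(cd1$broods, function(b) mean(rowMeans(b)), numeric(1))
  expect_lt(mean(abs(bm1 - cd1$parent_scores$midparent)), 0.03)
  expect_identical(names(cd1$broods), cd1$parent_scores$cross)
  expect_error(gen_cross_dataset(0.5, 10, 0, seed = 1), "brood_size")
  expect_error(gen_cross_dataset(0.5, 100, 10, pop_size = 100, seed = 1),
               "supplies only")
})

test_that("behavior matrices survive a CSV round trip", {
  m <- gen_choice_matrix(12, 8, seed = 3, missing_rate = 0.15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_behavior_csv(m, path)
  back <- read_behavior_csv(path, "choice")
  expect_equal(dim(back), dim(m))
  expect_equal(as.vector(back), as.vector(m))
  expect_identical(rownames(back), rownames(m))

  pm <- gen_position_matrix(5, 6, seed = 4)
  write_behavior_csv(pm, path)
  backp <- read_behavior_csv(path, "position")
  expect_equal(as.vector(backp), as.vector(pm), tolerance = 1e-12)
})
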