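# Experiment suite: structural invariants on reduced configurations.

exp_weather <- function() boston_normals()
exp_params <- function() model_params(beta = 0.102, delta = 0.0433)

test_that("strategy comparison is paired, signed, and degenerate-safe", {
  w <- exp_weather()
  g <- test_grid(31)
  rec <- compare_strategies(w, exp_params(), flavor = "det", grid = g,
                            n_age = 15)
  expect_true(is.finite(rec$advantage_pct))
  # swapping the strategy labels flips the sign of the advantage
  swapped <- (rec$final_at - rec$final_bh) / rec$final_bh * 100
  expect_equal(sign(swapped), -sign(rec$advantage_pct))

  p0 <- model_params(beta = 0.1, delta = 0.04,
                     pref_dist = pref_point(0.32))
  rec0 <- compare_strategies(w, p0, flavor = "det",
                             grid = pref_grid(p0$pref_dist, 31),
                             n_age = 15)
  expect_identical(rec0$advantage_pct, 0)

  # extinct AT arm is flagged, not reported as an infinite advantage
  dead <- model_params(beta = 0, delta = 1)
  recd <- compare_strategies(synthetic_normals(L = 30), dead,
                             flavor = "det", grid = g, n_age = 5)
  expect_true(recd$at_extinct)
  expect_true(is.na(recd$advantage_pct))
})

test_that("agent-flavor comparison attaches a Monte-Carlo SE", {
  w <- synthetic_normals(L = 60, T_start = 12, T_peak = 23, peak_day = 35)
  p <- model_params(beta = 0.08, delta = 0.03, n_seed = 100L)
  rec <- compare_strategies(w, p, flavor = "agent", reps = 8, seed = 3)
  expect_true(is.finite(rec$se) && rec$se > 0)
  rec2 <- compare_strategies(w, p, flavor = "agent", reps = 8, seed = 3)
  expect_identical(rec$advantage_pct, rec2$advantage_pct)
})

test_that("random-season ensembles are reproducible and summarized", {
  wm <- boston_weather_model(seed = 2, L = 120)
  p <- exp_params()
  g <- test_grid(21)
  e1 <- ensemble_random_seasons(4, wm, p, seed = 9, grid = g, n_age = 10)
  e2 <- ensemble_random_seasons(4, wm, p, seed = 9, grid = g, n_age = 10)
  expect_identical(e1$records, e2$records)
  expect_true(all(is.finite(e1$records$advantage_pct)))
  expect_true(e1$frac_bh >= 0 && e1$frac_bh <= 1)
  expect_length(e1$fits$mean_temp$coef, 3)

  acc <- multi_season_accumulation(4, wm, p, seed = 9, grid = g,
                                   n_age = 10)
  expect_equal(acc$cumulative,
               cumprod(1 + acc$advantage_pct / 100), tolerance = 1e-12)
})

test_that("climate offsets shift the balance toward adaptive tracking", {
  w <- exp_weather()
  p <- exp_params()
  g <- test_grid(31)
  sw <- climate_offset_sweep(c(0, 2), w, p, grid = g, n_age = 15)
  base <- compare_strategies(w, p, flavor = "det", grid = g, n_age = 15)
  expect_equal(sw$records$advantage_pct[sw$records$offset == 0],
               base$advantage_pct, tolerance = 1e-9)
  # a 2 C warming flips the advantage to AT under this configuration
  expect_lt(sw$records$advantage_pct[sw$records$offset == 2], 0)
  expect_gt(sw$records$advantage_pct[sw$records$offset == 0], 0)
  sw2 <- climate_offset_sweep(c(0, 1, 2), w, p, grid = g, n_age = 15)
  expect_true(is.finite(sw2$crossing_offset))
  expect_lte(sw2$crossing_offset, 2)
})

test_that("season-length identity holds and stretching changes length", {
  wm <- boston_weather_model(seed = 3, L = 120)
  p <- exp_params()
  g <- test_grid(21)
  sl <- season_length_sweep(c(60, 120), wm, p, n_per_length = 2,
                            seed = 4, grid = g, n_age = 10)
  expect_setequal(sl$by_length$length, c(60, 120))
  expect_true(all(is.finite(sl$records$advantage_pct)))
})

test_that("variance sweep reproduces the baseline and skips infeasible SDs", {
  w <- exp_weather()
  p <- exp_params()
  expect_warning(
    vs <- variance_sweep(c(0, 1, 10), p, w, grid_K = 31, n_age = 15),
    "infeasible")
  expect_setequal(unique(vs$scale), c(0, 1))
  pbh <- p
  pbh$strategy <- "BH"
  base_bh <- run_season_det(pbh, pref_grid(p$pref_dist, 31), w,
                            n_age = 15)$daily_pop[215]
  expect_equal(vs$final_pop[vs$scale == 1 & vs$strategy == "BH"],
               base_bh, tolerance = 1e-9)
  # zero variance: the two strategies are the same model
  expect_equal(vs$final_pop[vs$scale == 0 & vs$strategy == "BH"],
               vs$final_pop[vs$scale == 0 & vs$strategy == "AT"],
               tolerance = 1e-12)
})

test_that("plasticity strength zero is the baseline model", {
  w <- exp_weather()
  p <- exp_params()
  g <- test_grid(31)
  ps <- plasticity_sweep(c(0, 0.25), p, w, grid = g, n_age = 15)
  base <- compare_strategies(w, p, flavor = "det", grid = g, n_age = 15)
  expect_equal(ps$advantage_pct[ps$lambda == 0], base$advantage_pct,
               tolerance = 1e-12)
  # a moderate plasticity overlay leaves a positive BH advantage
  expect_gt(ps$advantage_pct[ps$lambda == 0.25], 0)
})
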