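# Weather module: CSV IO, synthetic normals, AR deviations, cloud
# surrogates, and season transforms.

test_that("weather CSV reading validates structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  w <- synthetic_normals(L = 214)
  write_weather(w, path)
  back <- read_weather(path)
  expect_equal(nrow(back), 214)
  expect_equal(back$t_normal, w$t_normal, tolerance = 1e-9)

  df <- utils::read.csv(path)
  df$cloud[5] <- 1.2
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_weather(path), "row\\(s\\): 5")

  df$cloud <- NULL; df$deviation <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_message(wd <- read_weather(path), "deviation")
  expect_true(all(wd$deviation == 0))

  df2 <- utils::read.csv(path)
  df2 <- df2[-3, ]
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_weather(path), "contiguous")
})

test_that("synthetic normals have the intended seasonal shape", {
  w <- synthetic_normals()
  expect_equal(nrow(w), 214)
  te <- effective_temperature(w)
  expect_gt(mean(te), 15); expect_lt(mean(te), 19)
  expect_true(all(diff(te[1:115]) >= -1e-12))  # nondecreasing to the peak
  expect_equal(max(te), 23.5, tolerance = 1e-9)
  expect_equal(te[1], 7, tolerance = 1e-9)

  wc <- synthetic_normals(T_start = 17.5, T_peak = 17.5)
  expect_true(all(abs(effective_temperature(wc) - 17.5) < 1e-12))
  expect_error(synthetic_normals(L = 100, peak_day = 150), "peak_day")
})

test_that("AR fitting is self-consistent", {
  set.seed(1)
  expect_error(fit_ar(rnorm(100), 30), "lower order")

  wn <- rnorm(3000)
  fw <- fit_ar(wn, 30)
  expect_lt(max(abs(fw$coefficients)), 0.1)
  expect_equal(fw$innovation_sd, 1, tolerance = 0.05)
  expect_true(fw$stationary)

  x <- as.numeric(stats::filter(rnorm(50000, 0, 1), 0.6,
                                method = "recursive"))
  f1 <- fit_ar(x, 30)
  expect_equal(f1$coefficients[1], 0.6, tolerance = 0.05)
  expect_lt(max(abs(f1$coefficients[-1])), 0.05)

  # fit -> simulate -> refit round trip
  y <- simulate_deviations(f1, 50000, seed = 2)
  f2 <- fit_ar(y, 30)
  expect_gt(cor(f1$coefficients, f2$coefficients), 0.9)
})

test_that("simulated deviations reproduce the model autocorrelation", {
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(20000, 0, 2), c(0.5, 0.2),
                                method = "recursive"))
  fit <- fit_ar(x, 30)
  y <- simulate_deviations(fit, 50000, seed = 4)
  acf_x <- as.numeric(acf(x, lag.max = 30, plot = FALSE)$acf)[-1]
  acf_y <- as.numeric(acf(y, lag.max = 30, plot = FALSE)$acf)[-1]
  expect_lt(max(abs(acf_x - acf_y)), 0.05)

  zero <- fit
  zero$innovation_sd <- 0
  expect_equal(simulate_deviations(zero, 50), rep(0, 50))
  expect_identical(simulate_deviations(fit, 100, seed = 9),
                   simulate_deviations(fit, 100, seed = 9))
  bad <- fit
  bad$coefficients[1] <- 1.05
  bad$stationary <- FALSE
  expect_error(simulate_deviations(bad, 50), "non-stationary")
})

test_that("simulated deviation seasons are mean-zero on average", {
  wm <- boston_weather_model(seed = 5)
  means <- vapply(1:100, function(i)
    mean(simulate_deviations(wm$ar, 214, seed = i)), numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-9)
})

test_that("cloud surrogates keep the marginal and the autocorrelation", {
  wm <- boston_weather_model(seed = 1)
  cl <- simulate_cloud(wm$cloud_hist, 214, seed = 2)
  expect_true(cl$success)
  expect_lt(abs(cl$r_original), 0.1)
  expect_gt(cl$r_acf, 0.998)
  # value conservation: every surrogate value is a historical value
  expect_true(all(cl$cloud %in% wm$cloud_hist))

  # iid history: a permutation of resampled values satisfies everything
  set.seed(6)
  iid <- runif(600)
  cli <- simulate_cloud(iid, 200, seed = 7)
  expect_true(cli$success)
  expect_error(simulate_cloud(runif(50), 200), "shorter")
})

test_that("season transforms offset and stretch as documented", {
  w <- boston_normals()
  expect_equal(effective_temperature(transform_season(w, offset = 0)),
               effective_temperature(w))
  expect_equal(effective_temperature(transform_season(w, offset = 2)),
               effective_temperature(w) + 2)

  short <- transform_season(w, stretch_to = 107)
  expect_equal(nrow(short), 107)
  back <- transform_season(short, stretch_to = 214)
  expect_lt(max(abs(back$t_normal - w$t_normal)), 0.5)
  expect_identical(transform_season(w, stretch_to = 214)$t_normal,
                   w$t_normal)
  expect_error(transform_season(w, stretch_to = 500), "stretch_to")
})
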