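degenerate_m1 <- function(series, rate, shape = 1e7) {
  new_posterior("M1", cbind(beta0 = log(rate), shape = shape), series)
}

obs_series <- function(n = 30, seed = 14, authors = NULL) {
  set.seed(seed)
  a <- authors %||% rep(1, n)
  yearly_series(2020 - n + 1:n, rnbinom(n, mu = 10, size = 2), a)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a concentrated constant-rate posterior forecasts ~ 50 * rate", {
  fit <- degenerate_m1(obs_series(), rate = 20)
  fc <- forecast_model(fit, forecast_config(n_paths = 4000, seed = 5))
  expect_equal(fc$summary$cumulative_mean, 1000, tolerance = 0.01)
  expect_identical(fc$cumulative_total, rowSums(fc$paths))
  expect_true(all(fc$paths >= 0))
})

test_that("credible intervals nest and forecasts are reproducible", {
  fit <- degenerate_m1(obs_series(), rate = 8, shape = 2)
  cfg <- forecast_config(n_paths = 1500, seed = 9)
  fc <- forecast_model(fit, cfg)
  ci90 <- fc$summary$cumulative_interval[["90%"]]
  ci95 <- fc$summary$cumulative_interval[["95%"]]
  expect_gte(ci90[1], ci95[1])
  expect_lte(ci90[2], ci95[2])
  expect_lt(ci90[1], ci90[2])
  fc2 <- forecast_model(fit, cfg)
  expect_identical(fc$paths, fc2$paths)
})

test_that("horizon must start after the fitted span", {
  fit <- degenerate_m1(obs_series(), rate = 5)
  expect_error(forecast_model(fit, forecast_config(first_year = 2019)),
               "horizon")
})

test_that("an AR model with a pinned-to-zero latent matches the non-AR model", {
  series <- obs_series()
  set.seed(3)
  base <- cbind(beta0 = rnorm(300, 2, 0.2), beta_year = rnorm(300, 0.1, 0.05),
                shape = runif(300, 1, 4))
  m2 <- new_posterior("M2", base, series)
  r0 <- matrix(0, 300, 30, dimnames = list(NULL, paste0("r[", 1:30, "]")))
  m3 <- new_posterior("M3", cbind(base, rho = 0, sigma_ar = 0, r0), series)
  cfg <- forecast_config(seed = 21)
  expect_identical(forecast_model(m2, cfg)$paths,
                   forecast_model(m3, cfg)$paths)
})

test_that("offset forecasts resample authors from the window pool", {
  a <- c(rep(2, 10), rep(c(0L, 5L), 10))  # 1991-2020; window has 2, 0s, 5s
  series <- obs_series(n = 30, authors = ifelse(a == 0, 0.1, a))
  draws <- cbind(beta0 = rep(log(4), 400), beta_year = 0,
                 shape = 1e7)
  fit <- new_posterior("M4", draws, series)
  fc <- forecast_model(fit, forecast_config(n_paths = 5, seed = 2))
  # window 2000-2020 (21 years) pools one 2, ten 0s (floored at 0.1) and
  # ten 5s; mean yearly count = rate * mean exposure
  expected <- 4 * (2 + 10 * 0.1 + 10 * 5) / 21
  expect_equal(mean(fc$paths), expected, tolerance = 0.05)
})

test_that("ensemble is a path mixture honoring the weights", {
  series <- obs_series()
  f_lo <- forecast_model(degenerate_m1(series, 5), forecast_config(n_paths = 500, seed = 1))
  f_hi <- forecast_model(degenerate_m1(series, 30), forecast_config(n_paths = 500, seed = 2))
  fcs <- list(M1 = f_lo, M2 = f_hi)
  # weight 1 on one model reproduces that model exactly
  ens1 <- forecast_ensemble(fcs, c(M1 = 1, M2 = 0), forecast_config(seed = 3))
  expect_identical(ens1$paths, f_lo$paths)
  expect_equal(ens1$model_id, "ensemble")
  # zero-weight models are never sampled
  ens2 <- forecast_ensemble(fcs, c(M1 = 0.999999, M2 = 0.000001),
                            forecast_config(seed = 3))
  expect_lt(max(ens2$cumulative_total), max(f_hi$cumulative_total))
  # a proper mixture lands between the component means and widens intervals
  ens <- forecast_ensemble(fcs, c(M1 = 0.5, M2 = 0.5), forecast_config(seed = 4))
  means <- c(f_lo$summary$cumulative_mean, f_hi$summary$cumulative_mean)
  expect_gte(ens$summary$cumulative_mean, min(means))
  expect_lte(ens$summary$cumulative_mean, max(means))
  ci <- ens$summary$cumulative_interval[["95%"]]
  expect_lte(ci[1], f_lo$summary$cumulative_interval[["95%"]][2])
  expect_gte(ci[2], f_hi$summary$cumulative_interval[["95%"]][1])
  expect_error(forecast_ensemble(fcs, c(M1 = 1)), "weights")
})

test_that("required_rate follows the closed form", {
  expect_equal(required_rate(1140, 50, 13), 1140 / 650)
  expect_equal(required_rate(100, 50, 2), 1)
  expect_equal(required_rate(0, 50, 13), 0)
  expect_error(required_rate(100, 50, 0), "taxonomists")
  expect_error(required_rate(100, 0, 13), "horizon")
})
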