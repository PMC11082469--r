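test_that("model specs encode the nested family", {
  specs <- all_model_specs()
  flags <- t(vapply(specs, function(s) {
    c(s$has_year, s$has_ar1, s$has_offset)
  }, logical(3)))
  expect_equal(unname(flags), rbind(
    c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE),
    c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE)))
  expect_equal(format(specs$M4_1),
               "count ~ year + offset(log(author)) + ar(p = 1)")
  expect_error(model_spec("M5"))
})

test_that("pointwise log-likelihood matches direct pmf evaluation", {
  set.seed(31)
  series <- yearly_series(1981:2000, rpois(20, 8), rep(2, 20))
  x <- year_transform(series)$transform(series$years)
  draws <- cbind(beta0 = rnorm(5, 2, 0.2), beta_year = rnorm(5, 0, 0.1),
                 shape = runif(5, 1, 4))
  fit <- new_posterior("M2", draws, series)
  ll <- log_likelihood_pointwise(fit)
  expect_equal(dim(ll), c(5, 20))
  direct <- sapply(seq_len(20), function(t) {
    nb_logpmf_lgamma(series$counts[t],
                     exp(draws[, "beta0"] + draws[, "beta_year"] * x[t]),
                     draws[, "shape"])
  })
  expect_equal(ll, direct, tolerance = 1e-10, ignore_attr = TRUE)
  # geometric special case through the posterior path
  s0 <- yearly_series(2000, 0L, 0.1)
  f0 <- new_posterior("M1", cbind(beta0 = 0, shape = 1), s0)
  expect_equal(unname(log_likelihood_pointwise(f0)[1, 1]), log(0.5))
})

test_that("nested models coincide at the pinned parameter values", {
  set.seed(77)
  series <- yearly_series(1951:2000, rpois(50, 10), rep(1, 50))
  n <- 50
  base <- cbind(beta0 = rnorm(8, 2.3, 0.3), shape = runif(8, 1, 5))
  m1 <- log_likelihood_pointwise(new_posterior("M1", base, series))
  # M2 with beta_year pinned at 0 equals M1
  m2_draws <- cbind(base, beta_year = 0)
  m2 <- log_likelihood_pointwise(new_posterior("M2", m2_draws, series))
  expect_equal(m2, m1)
  # M3 with the latent process pinned at 0 equals M2 (free beta_year)
  m2_free <- cbind(base, beta_year = rnorm(8, 0.2, 0.1))
  r0 <- matrix(0, 8, n, dimnames = list(NULL, paste0("r[", 1:n, "]")))
  m3_draws <- cbind(m2_free, rho = 0, sigma_ar = 0, r0)
  m3 <- log_likelihood_pointwise(new_posterior("M3", m3_draws, series))
  expect_equal(m3, log_likelihood_pointwise(new_posterior("M2", m2_free,
                                                          series)))
  # M4 at unit exposure equals M2
  m4 <- log_likelihood_pointwise(new_posterior("M4", m2_free, series))
  expect_equal(m4, log_likelihood_pointwise(new_posterior("M2", m2_free,
                                                          series)))
})

test_that("sampler configuration resolves draw targets and validates", {
  expect_error(sampler_config(chains = 1), "2 chains")
  expect_error(sampler_config(warmup_fraction = 1), "warmup_fraction")
  res <- taxoforecast:::resolve_sampler(sampler_config(), model_spec("M1"))
  expect_equal(res$iterations, 7500L)
  expect_gte(4 * floor(res$post / res$thin), 2600)
  res_ar <- taxoforecast:::resolve_sampler(sampler_config(),
                                           model_spec("M4_1"))
  expect_equal(res_ar$iterations, 15000L)
  expect_gte(4 * floor(res_ar$post / res_ar$thin), 5200)
})

test_that("fitting is reproducible given the seed", {
  set.seed(8)
  series <- yearly_series(1991:2020, rnbinom(30, mu = 10, size = 2),
                          rep(1, 30))
  cfg <- quick_sampler(seed = 13, iterations = 1200, target_draws = 300,
                       adapt = 200)
  f1 <- suppressWarnings(fit_description_model(series, "M1", cfg))
  f2 <- suppressWarnings(fit_description_model(series, "M1", cfg))
  expect_identical(f1$draws, f2$draws)
  expect_gte(nrow(f1$draws), 300)
})

test_that("a constant series yields no credible year trend", {
  series <- yearly_series(1961:2000, rep(5L, 40), rep(1, 40))
  fit <- suppressWarnings(fit_description_model(
    series, "M2", quick_sampler(seed = 3)))
  ci <- quantile(fit$draws[, "beta_year"], c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("the M1 posterior agrees with a 2-D grid-posterior oracle", {
  fx <- m1_grid_fixture()
  grid <- grid_posterior_m1(fx$series$counts, fx$fit$priors)
  rate_mean_fit <- mean(exp(fx$fit$draws[, "beta0"]))
  expect_gt(rate_mean_fit, grid$rate_quantile(0.01))
  expect_lt(rate_mean_fit, grid$rate_quantile(0.99))
  expect_equal(rate_mean_fit, grid$rate_mean, tolerance = 0.02)
})

test_that("doubling the author exposure shifts the intercept by -log(2)", {
  set.seed(55)
  a <- rpois(80, 6); a[a == 0] <- 1
  mu <- exp(1.2) * a
  counts <- rnbinom(80, mu = mu, size = 3)
  s1 <- yearly_series(1941:2020, counts, a)
  s2 <- yearly_series(1941:2020, counts, 2 * a)
  pri <- prior_set(intercept_loc = 1, intercept_scale = 2.5)
  cfg <- quick_sampler(seed = 17, iterations = 3000, target_draws = 800)
  f1 <- suppressWarnings(fit_description_model(s1, "M4", cfg, pri))
  f2 <- suppressWarnings(fit_description_model(s2, "M4", cfg, pri))
  shift <- mean(f2$draws[, "beta0"]) - mean(f1$draws[, "beta0"])
  mc_se <- sqrt(var(f1$draws[, "beta0"]) / 200 +
                  var(f2$draws[, "beta0"]) / 200)
  expect_equal(shift, -log(2), tolerance = max(0.05, 4 * mc_se))
})
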