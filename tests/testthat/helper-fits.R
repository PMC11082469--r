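# Small fits shared across test files, computed lazily and cached for the
# duration of the test run.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

quick_sampler <- function(seed = 11, chains = 2, iterations = 2400,
                          target_draws = 600, adapt = 400) {
  sampler_config(chains = chains, iterations = iterations,
                 target_draws = target_draws, adapt = adapt, seed = seed)
}

# i.i.d. NB series at the study's series length, for the grid-oracle check
iid_nb_series <- function(n = 268, mean = 20, shape = 2, seed = 42) {
  set.seed(seed)
  yearly_series(2020 - n + 1:n, rnbinom(n, mu = mean, size = shape),
                rep(1, n))
}

m1_grid_fixture <- function() {
  cached("m1_grid", {
    series <- iid_nb_series()
    fit <- suppressWarnings(fit_description_model(
      series, "M1", quick_sampler(seed = 5, iterations = 4000,
                                  target_draws = 1200)))
    list(series = series, fit = fit)
  })
}

# short series + M1 fit used by the PSIS-vs-exact-LOO check
m1_short_fixture <- function() {
  cached("m1_short", {
    set.seed(99)
    series <- yearly_series(2001:2020, rnbinom(20, mu = 12, size = 2),
                            rep(1, 20))
    fit <- suppressWarnings(fit_description_model(
      series, "M1", quick_sampler(seed = 21, iterations = 3000,
                                  target_draws = 800)))
    list(series = series, fit = fit)
  })
}
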