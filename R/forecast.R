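#' Forecast configuration
#'
#' Defaults reproduce the study conditions: a 2021-2070 horizon, with future
#' author counts for offset models resampled from the observed 2000-2020
#' values.
#'
#' @param first_year,last_year Inclusive forecast horizon.
#' @param author_window Calendar window whose observed raw author counts form
#'   the resampling pool for future taxonomic effort.
#' @param n_paths Simulated paths per retained posterior draw.
#' @param seed Integer RNG seed.
#' @param levels Credible-interval levels for summaries.
#' @return A list of class `forecast_config`.
#' @export
forecast_config <- function(first_year = 2021, last_year = 2070,
                            author_window = c(2000, 2020), n_paths = 1,
                            seed = 1, levels = c(0.90, 0.95)) {
  if (last_year < first_year) stop("empty horizon", call. = FALSE)
  if (n_paths < 1) stop("`n_paths` must be >= 1", call. = FALSE)
  structure(list(first_year = as.integer(first_year),
                 last_year = as.integer(last_year),
                 author_window = as.integer(author_window),
                 n_paths = as.integer(n_paths), seed = as.integer(seed),
                 levels = sort(levels)),
            class = "forecast_config")
}

forecast_summary <- function(years, paths, levels) {
  cumulative <- rowSums(paths)
  ints <- lapply(levels, function(lv) {
    a <- (1 - lv) / 2
    stats::quantile(cumulative, c(a, 1 - a), names = FALSE)
  })
  names(ints) <- paste0(levels * 100, "%")
  yearly <- data.frame(year = years, mean = colMeans(paths))
  for (lv in levels) {
    a <- (1 - lv) / 2
    q <- apply(paths, 2, stats::quantile, probs = c(a, 1 - a))
    yearly[[sprintf("lower%g", lv * 100)]] <- q[1, ]
    yearly[[sprintf("upper%g", lv * 100)]] <- q[2, ]
  }
  list(cumulative_mean = mean(cumulative),
       cumulative_median = stats::median(cumulative),
       cumulative_interval = ints, yearly = yearly)
}

#' Forecast future description counts from one fitted model
#'
#' Simulates yearly description counts over the forecast horizon from each
#' retained posterior draw. The year covariate continues the transform
#' fitted on the observed span. For AR models the latent residual is
#' propagated forward from the draw's own final fitted residual
#' (`r[T+1] = rho * r[T] + Normal(0, sigma_ar)`). For offset models a future
#' author count is drawn i.i.d. (per draw, per year) with replacement from
#' the raw observed author counts in the configured window and re-floored at
#' 0.1 before logging. Counts are then drawn from the negative binomial
#' observation model.
#'
#' @param fit An `nb_fit` from [fit_description_model()].
#' @param cfg A [forecast_config()].
#' @param force Simulate even if the fit is flagged non-converged.
#' @return Object of class `description_forecast`: `model_id`, `years`,
#'   `paths` (draws x years integer matrix), `cumulative_total` (per draw),
#'   and `summary` (means and credible intervals).
#' @export
forecast_model <- function(fit, cfg = forecast_config(), force = FALSE) {
  stopifnot(inherits(fit, "nb_fit"))
  series <- fit$series
  if (cfg$first_year <= series$span[2]) {
    stop("forecast horizon must start after the end of the fitted series",
         call. = FALSE)
  }
  if (!fit$converged && !force) {
    stop("fit is flagged non-converged; pass force = TRUE to forecast anyway",
         call. = FALSE)
  }
  # each simulation stage draws from its own seeded substream, so models that
  # coincide on a stage (e.g. an AR model with sigma_ar = 0 vs the non-AR
  # model with matched draws) produce identical observation draws
  years <- cfg$first_year:cfg$last_year
  h <- length(years)
  draws <- fit$draws
  ndraw <- nrow(draws)
  npath <- ndraw * cfg$n_paths
  idx <- rep(seq_len(ndraw), each = cfg$n_paths)

  eta <- matrix(draws[idx, "beta0"], npath, h)
  if (fit$spec$has_year) {
    x_future <- fit$transform$transform(years)
    eta <- eta + outer(draws[idx, "beta_year"], x_future)
  }
  if (fit$spec$has_offset) {
    set.seed(cfg$seed + 1L)
    pool <- authors_raw(series)[series$years >= cfg$author_window[1] &
                                  series$years <= cfg$author_window[2]]
    a <- matrix(sample(pool, npath * h, replace = TRUE), npath, h)
    a[a == 0] <- 0.1
    eta <- eta + log(a)
  }
  if (fit$spec$has_ar1) {
    set.seed(cfg$seed + 2L)
    n_obs <- length(series$years)
    rT <- draws[idx, paste0("r[", n_obs, "]")]
    rho <- draws[idx, "rho"]
    sig <- draws[idx, "sigma_ar"]
    r <- rT
    for (j in seq_len(h)) {
      r <- rho * r + stats::rnorm(npath, 0, sig)
      eta[, j] <- eta[, j] + r
    }
  }
  shape <- draws[idx, "shape"]
  set.seed(cfg$seed + 3L)
  paths <- matrix(stats::rnbinom(npath * h, mu = exp(eta),
                                 size = matrix(shape, npath, h)),
                  npath, h)
  colnames(paths) <- years
  structure(list(model_id = fit$spec$id, years = years, paths = paths,
                 cumulative_total = rowSums(paths),
                 summary = forecast_summary(years, paths, cfg$levels)),
            class = "description_forecast")
}

#' Combine per-model forecasts into an elpd-weighted ensemble
#'
#' Forms the ensemble as a mixture over whole simulated paths: each ensemble
#' path is drawn from one component model chosen with probability equal to
#' its weight, then sampled uniformly (with replacement) from that model's
#' paths. Mixing whole paths, rather than averaging summaries, lets the
#' ensemble's credible interval span beyond any single model's interval when
#' the component forecasts disagree.
#'
#' @param forecasts Named list of [forecast_model()] results sharing one
#'   horizon.
#' @param weights Named numeric weights (from [elpd_weights()]) covering
#'   every forecast; normalized internally.
#' @param cfg A [forecast_config()] (horizon must match; its seed drives the
#'   mixture sampling).
#' @return A `description_forecast` with `model_id = "ensemble"`.
#' @export
forecast_ensemble <- function(forecasts, weights, cfg = forecast_config()) {
  if (is.null(names(forecasts))) {
    names(forecasts) <- vapply(forecasts, `[[`, character(1), "model_id")
  }
  if (!setequal(names(weights), names(forecasts))) {
    stop("`weights` must name exactly the supplied forecasts", call. = FALSE)
  }
  years <- forecasts[[1]]$years
  for (f in forecasts) {
    if (!identical(f$years, years)) {
      stop("all forecasts must share the same horizon", call. = FALSE)
    }
  }
  weights <- weights[names(forecasts)] / sum(weights)
  if (any(weights == 1)) {
    # a one-component mixture is the component itself
    out <- forecasts[[names(weights)[weights == 1]]]
    out$model_id <- "ensemble"
    return(out)
  }
  set.seed(cfg$seed + 4L)
  n_out <- max(vapply(forecasts, function(f) nrow(f$paths), integer(1)))
  pick <- sample(names(forecasts), n_out, replace = TRUE, prob = weights)
  paths <- matrix(0L, n_out, length(years))
  for (m in unique(pick)) {
    rows <- which(pick == m)
    src <- forecasts[[m]]$paths
    paths[rows, ] <- src[sample(nrow(src), length(rows), replace = TRUE), ]
  }
  colnames(paths) <- years
  structure(list(model_id = "ensemble", years = years, paths = paths,
                 cumulative_total = rowSums(paths),
                 summary = forecast_summary(years, paths, cfg$levels)),
            class = "description_forecast")
}

#' @export
print.description_forecast <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<description_forecast %s> %d-%d, %d paths\n", x$model_id,
              x$years[1], x$years[length(x$years)], nrow(x$paths)))
  cat(sprintf("  cumulative descriptions: mean %.0f", s$cumulative_mean))
  for (nm in names(s$cumulative_interval)) {
    ci <- s$cumulative_interval[[nm]]
    cat(sprintf("; %s CrI [%.0f, %.0f]", nm, ci[1], ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' Required description rate per taxonomist
#'
#' Translates a cumulative forecast into the yearly per-taxonomist
#' description rate needed to realize it: `total / (horizon_years *
#' taxonomists)`.
#'
#' @param ensemble_total Forecast cumulative number of descriptions.
#' @param horizon_years Length of the forecast horizon in years.
#' @param taxonomists Number of active taxonomists (e.g. the median yearly
#'   author count from [median_authors()]).
#' @return Descriptions per year per taxonomist.
#' @export
required_rate <- function(ensemble_total, horizon_years, taxonomists) {
  if (horizon_years <= 0) stop("`horizon_years` must be positive", call. = FALSE)
  if (taxonomists <= 0) stop("`taxonomists` must be positive", call. = FALSE)
  if (ensemble_total < 0) stop("`ensemble_total` must be non-negative",
                               call. = FALSE)
  ensemble_total / (horizon_years * taxonomists)
}
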