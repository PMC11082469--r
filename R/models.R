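#' Specification of one nested description-rate model
#'
#' The five nested models of yearly description counts share a negative
#' binomial observation model with log link and differ in the linear
#' predictor:
#' \describe{
#'   \item{M1}{`count ~ 1` — constant description rate.}
#'   \item{M2}{`count ~ year` — log-linear trend in time.}
#'   \item{M3}{`count ~ year + ar(1)` — adds a latent first-order
#'     autoregressive process on the log mean.}
#'   \item{M4}{`count ~ year + offset(log(author))` — adds the logged yearly
#'     unique-author count as an exposure offset, turning the trend into a
#'     per-author description rate.}
#'   \item{M4_1}{`count ~ year + offset(log(author)) + ar(1)` — both.}
#' }
#'
#' @param id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`, `"M4_1"`.
#' @return A list of class `model_spec` with flags `has_year`, `has_ar1`,
#'   `has_offset`.
#' @export
model_spec <- function(id = c("M1", "M2", "M3", "M4", "M4_1")) {
  id <- match.arg(id)
  flags <- switch(id,
    M1   = c(FALSE, FALSE, FALSE),
    M2   = c(TRUE,  FALSE, FALSE),
    M3   = c(TRUE,  TRUE,  FALSE),
    M4   = c(TRUE,  FALSE, TRUE),
    M4_1 = c(TRUE,  TRUE,  TRUE))
  structure(list(id = id, has_year = flags[1], has_ar1 = flags[2],
                 has_offset = flags[3]),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  rhs <- c(if (x$has_year) "year" else "1",
           if (x$has_offset) "offset(log(author))",
           if (x$has_ar1) "ar(p = 1)")
  paste("count ~", paste(rhs, collapse = " + "))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s> %s\n", x$id, format(x)))
  invisible(x)
}

#' All five model specifications
#' @return Named list of [model_spec()] objects.
#' @export
all_model_specs <- function() {
  ids <- c("M1", "M2", "M3", "M4", "M4_1")
  stats::setNames(lapply(ids, model_spec), ids)
}

#' MCMC sampler configuration
#'
#' Defaults reproduce the study conditions: four chains of 7500 iterations
#' (15000 when a latent AR(1) process is present), half discarded as warmup,
#' thinned to retain at least `target_draws` post-warmup samples (2600, or
#' 5200 with AR).
#'
#' @param chains Number of chains (>= 2).
#' @param iterations Total iterations per chain; `NULL` picks 7500/15000 by
#'   model complexity.
#' @param warmup_fraction Fraction of iterations discarded as warmup.
#' @param target_draws Minimum total retained post-warmup draws; `NULL`
#'   picks 2600/5200 by model complexity.
#' @param adapt Adaptation steps before warmup.
#' @param seed Integer RNG seed; each chain gets `seed + chain`.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, iterations = NULL,
                           warmup_fraction = 0.5, target_draws = NULL,
                           adapt = 1000, seed = 1) {
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (warmup_fraction <= 0 || warmup_fraction >= 1) {
    stop("`warmup_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(chains = as.integer(chains), iterations = iterations,
                 warmup_fraction = warmup_fraction,
                 target_draws = target_draws, adapt = as.integer(adapt),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

resolve_sampler <- function(cfg, spec) {
  iters <- cfg$iterations %||% if (spec$has_ar1 || spec$has_offset) 15000L else 7500L
  target <- cfg$target_draws %||% if (spec$has_ar1 || spec$has_offset) 5200L else 2600L
  warmup <- as.integer(round(iters * cfg$warmup_fraction))
  post <- iters - warmup
  thin <- max(1L, floor(cfg$chains * post / target))
  if (floor(post / thin) * cfg$chains < target) thin <- 1L
  list(iterations = iters, warmup = warmup, post = post, thin = thin,
       target = target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prior set for the description-rate models
#'
#' Weakly informative defaults: the intercept gets a Student-t(3) prior
#' centered on the median log count with scale 2.5 times the MAD of the log
#' counts (floored at 2.5); the year slope (on the centered and scaled
#' covariate) a Normal(0, 5); the NB shape a Gamma(0.01, 0.01); the AR(1)
#' coefficient a Uniform(-1, 1); and the AR innovation scale a half
#' Student-t(3, 0, 2.5).
#'
#' @param intercept_loc,intercept_scale Location/scale of the intercept
#'   prior; `NULL` derives them from the series at fit time.
#' @param intercept_df Degrees of freedom of the intercept prior.
#' @param slope_sd SD of the Normal prior on the year slope.
#' @param shape_rate,shape_shape Gamma prior parameters for the NB shape.
#' @param sigma_ar_scale Scale of the half-t prior on the AR innovation SD.
#' @return A list of class `prior_set`.
#' @export
prior_set <- function(intercept_loc = NULL, intercept_scale = NULL,
                      intercept_df = 3, slope_sd = 5,
                      shape_shape = 0.01, shape_rate = 0.01,
                      sigma_ar_scale = 2.5) {
  structure(list(intercept_loc = intercept_loc,
                 intercept_scale = intercept_scale,
                 intercept_df = intercept_df, slope_sd = slope_sd,
                 shape_shape = shape_shape, shape_rate = shape_rate,
                 sigma_ar_scale = sigma_ar_scale),
            class = "prior_set")
}

resolve_priors <- function(priors, series) {
  yl <- log1p(series$counts)
  loc <- priors$intercept_loc %||% stats::median(yl)
  scl <- priors$intercept_scale %||% max(2.5, 2.5 * stats::mad(yl))
  p <- priors
  p$intercept_loc <- loc
  p$intercept_scale <- scl
  p
}

#' Centered and scaled year covariate
#'
#' Years are centered at the span midpoint (mean year) and scaled to unit
#' standard deviation before sampling; forecasts continue the same transform
#' beyond the fitted span.
#'
#' @param series A [yearly_series()].
#' @return List with `center`, `scale`, and `transform(years)`.
#' @export
year_transform <- function(series) {
  ctr <- mean(series$years)
  scl <- stats::sd(series$years)
  list(center = ctr, scale = scl,
       transform = function(years) (years - ctr) / scl)
}

jags_model_code <- function(spec) {
  eta <- c("beta0",
           if (spec$has_year) "beta_year * x[t]",
           if (spec$has_offset) "log_a[t]",
           if (spec$has_ar1) "r[t]")
  paste0(
    "model {\n",
    if (spec$has_ar1) paste0(
      "  r[1] ~ dnorm(0, tau_ar * (1 - rho^2))\n",
      "  for (t in 2:n) { r[t] ~ dnorm(rho * r[t-1], tau_ar) }\n") else "",
    "  for (t in 1:n) {\n",
    "    y[t] ~ dnegbin(p[t], shape)\n",
    "    p[t] <- shape / (shape + mu[t])\n",
    "    log(mu[t]) <- ", paste(eta, collapse = " + "), "\n",
    "  }\n",
    "  beta0 ~ dt(int_loc, int_tau, int_df)\n",
    if (spec$has_year) "  beta_year ~ dnorm(0, slope_tau)\n" else "",
    "  shape ~ dgamma(shape_shape, shape_rate)\n",
    if (spec$has_ar1) paste0(
      "  rho ~ dunif(-1, 1)\n",
      "  sigma_ar ~ dt(0, sigma_tau, 3) T(0,)\n",
      "  tau_ar <- pow(sigma_ar, -2)\n") else "",
    "}\n")
}

split_rhat <- function(draws_by_chain) {
  # draws_by_chain: list of numeric vectors (one per chain); split each in half
  halves <- unlist(lapply(draws_by_chain, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a description-rate model by MCMC
#'
#' Draws from the posterior of one nested negative-binomial model given a
#' yearly series, using Gibbs/Metropolis sampling via JAGS. The fit is
#' reproducible: each chain's RNG is seeded from `cfg$seed`. Convergence is
#' assessed by split-chain R-hat (gate 1.01) and effective sample size
#' (gate 400) on the top-level parameters; violations produce a warning and
#' a `converged = FALSE` flag, never a silent pass.
#'
#' @param series A [yearly_series()].
#' @param spec A [model_spec()] (or a model id string).
#' @param cfg A [sampler_config()].
#' @param priors A [prior_set()].
#' @return An object of class `nb_fit`: `spec`, `draws` (matrix with columns
#'   `beta0`, `beta_year`*, `rho`*, `sigma_ar`*, `shape`, and `r[t]` latent
#'   residual columns for AR models; * where applicable), `series`,
#'   `transform` (year covariate transform), `priors` (resolved),
#'   `diagnostics` (R-hat and ESS per parameter), `converged`, `cfg`.
#' @export
fit_description_model <- function(series, spec, cfg = sampler_config(),
                                  priors = prior_set()) {
  stopifnot(inherits(series, "yearly_series"))
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  n <- length(series$years)
  res <- resolve_sampler(cfg, spec)
  pri <- resolve_priors(priors, series)
  tf <- year_transform(series)

  data <- list(y = series$counts, n = n,
               int_loc = pri$intercept_loc,
               int_tau = pri$intercept_scale^-2,
               int_df = pri$intercept_df,
               shape_shape = pri$shape_shape, shape_rate = pri$shape_rate)
  if (spec$has_year) {
    data$x <- tf$transform(series$years)
    data$slope_tau <- pri$slope_sd^-2
  }
  if (spec$has_offset) data$log_a <- log(series$authors)
  if (spec$has_ar1) data$sigma_tau <- pri$sigma_ar_scale^-2

  inits <- lapply(seq_len(cfg$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = cfg$seed + i)
  })
  monitors <- c("beta0",
                if (spec$has_year) "beta_year",
                if (spec$has_ar1) c("rho", "sigma_ar"),
                "shape",
                if (spec$has_ar1) "r")

  jm <- rjags::jags.model(textConnection(jags_model_code(spec)), data = data,
                          inits = inits, n.chains = cfg$chains,
                          n.adapt = cfg$adapt, quiet = TRUE)
  stats::update(jm, res$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = res$post,
                              thin = res$thin, progress.bar = "none")

  top <- c("beta0", if (spec$has_year) "beta_year",
           if (spec$has_ar1) c("rho", "sigma_ar"), "shape")
  rhat <- vapply(top, function(p) {
    split_rhat(lapply(samp, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- vapply(top, function(p) {
    sum(vapply(samp, function(ch) coda::effectiveSize(ch[, p]), numeric(1)))
  }, numeric(1))
  converged <- all(rhat <= 1.01, na.rm = TRUE) && all(ess >= 400)
  if (!converged) {
    warning(sprintf(
      "fit %s may not have converged (max R-hat %.3f, min ESS %.0f)",
      spec$id, max(rhat, na.rm = TRUE), min(ess)), call. = FALSE)
  }

  draws <- do.call(rbind, lapply(samp, as.matrix))
  # beta_year per calendar year for reporting
  structure(list(spec = spec, draws = draws, series = series,
                 transform = tf, priors = pri,
                 diagnostics = list(rhat = rhat, ess = ess,
                                    retained = nrow(draws),
                                    thin = res$thin,
                                    iterations = res$iterations),
                 converged = converged, cfg = cfg),
            class = "nb_fit")
}

#' Construct a posterior object from explicit draws
#'
#' Low-level constructor used to build `nb_fit`-compatible objects from a
#' known set of parameter draws (e.g. degenerate single-draw posteriors in
#' analytic checks, or matched-draw comparisons across nested models).
#'
#' @param spec A [model_spec()] or id string.
#' @param draws Matrix with named columns `beta0`, `shape`, and as required
#'   `beta_year`, `rho`, `sigma_ar`, and latent `r[1]`..`r[n]`.
#' @param series The [yearly_series()] the draws refer to.
#' @return An `nb_fit` object (marked converged, no diagnostics).
#' @export
new_posterior <- function(spec, draws, series) {
  if (is.character(spec)) spec <- model_spec(spec)
  draws <- as.matrix(draws)
  need <- c("beta0", "shape", if (spec$has_year) "beta_year",
            if (spec$has_ar1) c("rho", "sigma_ar"))
  missing <- setdiff(need, colnames(draws))
  if (length(missing)) stop("draws lack column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  structure(list(spec = spec, draws = draws, series = series,
                 transform = year_transform(series), priors = NULL,
                 diagnostics = NULL, converged = TRUE, cfg = NULL),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit %s> %s\n", x$spec$id, format(x$spec)))
  cat(sprintf("  %d retained draws; converged: %s\n",
              nrow(x$draws), x$converged))
  top <- intersect(c("beta0", "beta_year", "rho", "sigma_ar", "shape"),
                   colnames(x$draws))
  s <- t(apply(x$draws[, top, drop = FALSE], 2, function(v) {
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))
  }))
  print(round(s, 3))
  invisible(x)
}

fitted_log_mean <- function(fit, series) {
  draws <- fit$draws
  n <- length(series$years)
  eta <- matrix(draws[, "beta0"], nrow(draws), n)
  if (fit$spec$has_year) {
    x <- fit$transform$transform(series$years)
    eta <- eta + outer(draws[, "beta_year"], x)
  }
  if (fit$spec$has_offset) {
    eta <- eta + matrix(log(series$authors), nrow(draws), n, byrow = TRUE)
  }
  if (fit$spec$has_ar1) {
    rcols <- paste0("r[", seq_len(n), "]")
    if (!all(rcols %in% colnames(draws))) {
      stop("AR model draws lack latent residual columns", call. = FALSE)
    }
    eta <- eta + draws[, rcols]
  }
  eta
}

#' Pointwise log-likelihood matrix
#'
#' Log density of each observed yearly count under each retained posterior
#' draw; the draws-by-years matrix consumed by leave-one-out
#' cross-validation. AR models condition on the draw's own latent residuals.
#'
#' @param fit An `nb_fit`.
#' @param series The fitted [yearly_series()] (must match the fit's span).
#' @return Matrix, rows = draws, columns = years.
#' @export
log_likelihood_pointwise <- function(fit, series = fit$series) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!identical(as.integer(series$span), as.integer(fit$series$span))) {
    stop("series span does not match the fitted span", call. = FALSE)
  }
  eta <- fitted_log_mean(fit, series)
  shape <- fit$draws[, "shape"]
  n <- length(series$years)
  ll <- matrix(NA_real_, nrow(eta), n)
  for (t in seq_len(n)) {
    ll[, t] <- nb_logpmf(series$counts[t], exp(eta[, t]), shape)
  }
  colnames(ll) <- series$years
  ll
}
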