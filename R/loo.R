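# Pareto-smoothed importance sampling leave-one-out cross-validation.
# The generalized Pareto tail fit follows the Zhang & Stephens (2009)
# profile-posterior estimator with a weak prior pulling k toward 0.5.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fit a generalized Pareto distribution to tail exceedances
#'
#' Estimates the shape `k` and scale `sigma` of a generalized Pareto
#' distribution from positive exceedances, via the Zhang–Stephens
#' profile-posterior-mean method. `k` is regularized toward 0.5 with a weak
#' prior, stabilizing the estimate at small tail sizes.
#'
#' @param z Positive exceedances over the tail threshold.
#' @return List with `k` and `sigma`.
#' @keywords internal
gpd_fit <- function(z) {
  z <- sort(z)
  n <- length(z)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  theta <- 1 / z[n] + (1 - sqrt(m / (j - 0.5))) / (3 * z[max(1L, floor(n / 4 + 0.5))])
  k_j <- vapply(theta, function(th) -mean(log1p(-th * z)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(l_j, function(l) sum(exp(l_j - l)), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * z))
  sigma <- -k / theta_hat
  k <- (n * k + 5) / (n + 10)  # weak prior: 10 pseudo-obs at k = 0.5
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

psis_smooth <- function(lw, tail_fraction = 0.2) {
  # lw: log importance ratios for one observation (already max-centered ok)
  s <- length(lw)
  m <- ceiling(tail_fraction * s)
  k_hat <- Inf
  if (m >= 5 && s - m >= 1) {
    ord <- order(lw)
    tail_ids <- ord[(s - m + 1):s]
    cutoff <- lw[ord[s - m]]
    exc <- exp(lw[tail_ids]) - exp(cutoff)
    if (all(is.finite(exc)) && max(exc) > 0) {
      fit <- gpd_fit(exc[exc > 0] + max(exc) * 1e-12)
      k_hat <- fit$k
      if (is.finite(fit$k) && fit$sigma > 0) {
        q <- vapply((seq_len(m) - 0.5) / m, gpd_quantile, numeric(1),
                    k = fit$k, sigma = fit$sigma)
        smoothed <- log(exp(cutoff) + q)
        # order statistics replace the sorted tail; cap at the raw maximum
        smoothed <- pmin(smoothed, max(lw))
        lw[tail_ids] <- smoothed
      }
    } else {
      k_hat <- -Inf  # degenerate tail (all ratios equal): nothing to smooth
    }
  }
  list(lw = lw - log_sum_exp(lw), k = k_hat)
}

#' PSIS leave-one-out cross-validation from a log-likelihood matrix
#'
#' Computes the expected log predictive density (elpd) under leave-one-out
#' cross-validation, approximated by Pareto-smoothed importance sampling of
#' the posterior draws: for each observation the importance ratios
#' (reciprocal pointwise likelihoods) have their upper tail (20% of draws by
#' default) replaced by order statistics of a fitted generalized Pareto
#' distribution, truncated at the raw maximum. The Pareto shape diagnostic
#' `k` is returned per observation; values above 0.7 are flagged as
#' unreliable (not fatal). If the tail cannot be fit (too few draws or a
#' degenerate tail) the raw truncated ratios are used and a warning logged.
#'
#' @param loglik Matrix of pointwise log-likelihood values, rows = posterior
#'   draws (>= 100), columns = observations
#'   (see [log_likelihood_pointwise()]).
#' @param tail_fraction Fraction of draws treated as the importance-ratio
#'   tail. Default 0.2.
#' @param model_id Optional label carried into comparison tables.
#' @return Object of class `psis_loo`: `elpd_loo`, `se_elpd`,
#'   `pointwise` (per-observation elpd), `pareto_k`, `n_flagged`
#'   (observations with k > 0.7), `model_id`.
#' @export
psis_loo <- function(loglik, tail_fraction = 0.2, model_id = NULL) {
  loglik <- as.matrix(loglik)
  if (!all(is.finite(loglik))) stop("log-likelihood matrix must be finite",
                                    call. = FALSE)
  s <- nrow(loglik); n <- ncol(loglik)
  if (s < 100) stop("at least 100 posterior draws are required", call. = FALSE)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lr <- -ll            # log importance ratios r = 1 / p(y_i | theta)
    lr <- lr - max(lr)
    sm <- psis_smooth(lr, tail_fraction)
    pointwise[i] <- log_sum_exp(sm$lw + ll)
    pareto_k[i] <- sm$k
  }
  if (any(!is.finite(pareto_k))) {
    warning("Pareto tail fit unavailable for ",
            sum(!is.finite(pareto_k)),
            " observation(s); raw truncated weights used", call. = FALSE)
    pareto_k[!is.finite(pareto_k)] <- NA_real_
  }
  n_flagged <- sum(pareto_k > 0.7, na.rm = TRUE)
  if (n_flagged > 0) {
    warning(n_flagged, " observation(s) with Pareto k > 0.7; ",
            "their elpd contributions may be unreliable", call. = FALSE)
  }
  structure(list(elpd_loo = sum(pointwise),
                 se_elpd = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k,
                 n_flagged = n_flagged, model_id = model_id),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("<psis_loo%s> elpd_loo = %.1f (SE %.1f), n = %d\n",
              if (is.null(x$model_id)) "" else paste0(" ", x$model_id),
              x$elpd_loo, x$se_elpd, length(x$pointwise)))
  if (x$n_flagged > 0) cat(sprintf("  %d Pareto k > 0.7\n", x$n_flagged))
  invisible(x)
}

#' Compare models by elpd difference to the best
#'
#' Ranks a set of `psis_loo` results and computes each model's elpd
#' difference to the best-supported model, with the standard error of the
#' difference taken over the paired pointwise elpd contributions
#' (`se = sqrt(n * var(pointwise_m - pointwise_best))`). The best model gets
#' a difference of 0 with SE 0.
#'
#' @param loos Named list of [psis_loo()] results over the same observations.
#' @return A `data.frame` of class `loo_compare` sorted by decreasing elpd,
#'   with columns `model`, `elpd_loo`, `se_elpd`, `delta_elpd`, `se_delta`.
#' @export
loo_compare_models <- function(loos) {
  if (is.null(names(loos)) || any(!nzchar(names(loos)))) {
    names(loos) <- vapply(seq_along(loos), function(i) {
      loos[[i]]$model_id %||% paste0("model", i)
    }, character(1))
  }
  n_obs <- unique(vapply(loos, function(l) length(l$pointwise), integer(1)))
  if (length(n_obs) != 1) {
    stop("all models must be evaluated on the same observations",
         call. = FALSE)
  }
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- names(loos)[which.max(elpd)]
  pw_best <- loos[[best]]$pointwise
  delta <- elpd - max(elpd)
  se_delta <- vapply(names(loos), function(m) {
    if (m == best) 0 else sqrt(n_obs * stats::var(loos[[m]]$pointwise - pw_best))
  }, numeric(1))
  out <- data.frame(model = names(loos), elpd_loo = unname(elpd),
                    se_elpd = vapply(loos, `[[`, numeric(1), "se_elpd"),
                    delta_elpd = unname(delta), se_delta = unname(se_delta),
                    row.names = NULL)
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  class(out) <- c("loo_compare", "data.frame")
  out
}

#' Ensemble model weights from elpd
#'
#' Converts leave-one-out elpd values into normalized model weights. The
#' default `"pseudo_bma"` rule is the softmax of the elpd values
#' (`w_m = exp(elpd_m - max) / sum(...)`), computed with max-subtraction for
#' stability; it is invariant to adding a constant to every elpd.
#' `"stacking"` instead maximizes the leave-one-out log score of the weighted
#' predictive mixture over the simplex.
#'
#' @param loos Named list of [psis_loo()] results.
#' @param method `"pseudo_bma"` (default) or `"stacking"`.
#' @return Named numeric vector of weights summing to 1.
#' @export
elpd_weights <- function(loos, method = c("pseudo_bma", "stacking")) {
  method <- match.arg(method)
  if (length(loos) == 0) stop("at least one model is required", call. = FALSE)
  if (is.null(names(loos)) || any(!nzchar(names(loos)))) {
    names(loos) <- vapply(seq_along(loos), function(i) {
      loos[[i]]$model_id %||% paste0("model", i)
    }, character(1))
  }
  if (method == "pseudo_bma") {
    elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
    w <- exp(elpd - max(elpd))
    return(w / sum(w))
  }
  # stacking: maximize sum_i log sum_m w_m exp(pointwise_mi)
  pw <- do.call(cbind, lapply(loos, `[[`, "pointwise"))  # n x M
  M <- ncol(pw)
  if (M == 1) return(stats::setNames(1, colnames(pw)))
  obj <- function(a) {  # softmax parameterization keeps w on the simplex
    w <- exp(c(a, 0)); w <- w / sum(w)
    -sum(apply(pw, 1, function(lp) log_sum_exp(lp + log(w))))
  }
  opt <- stats::optim(rep(0, M - 1), obj, method = "BFGS")
  w <- exp(c(opt$par, 0)); w <- w / sum(w)
  stats::setNames(w, names(loos))
}
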