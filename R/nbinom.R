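#' Negative binomial log probability mass (mean/shape parameterization)
#'
#' Log pmf of the negative binomial distribution parameterized by its mean
#' \eqn{\mu} and shape (dispersion) \eqn{\phi}, so that
#' \eqn{\mathrm{Var}(Y) = \mu + \mu^2/\phi}. As \eqn{\phi \to \infty} the
#' distribution approaches a Poisson with rate \eqn{\mu}. This is the
#' observation model shared by all description-rate models in the package.
#'
#' @param y Non-negative integer count (vectorized).
#' @param mean Positive mean \eqn{\mu} (vectorized, recycled against `y`).
#' @param shape Positive shape \eqn{\phi} (vectorized, recycled).
#' @return Log probability mass, same length as the recycled arguments.
#' @examples
#' nb_logpmf(0, mean = 1, shape = 1) # log(1/2)
#' @export
nb_logpmf <- function(y, mean, shape) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("`mean` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(shape)) || any(shape <= 0)) {
    stop("`shape` must be positive and finite", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be a non-negative integer count", call. = FALSE)
  }
  stats::dnbinom(y, mu = mean, size = shape, log = TRUE)
}
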