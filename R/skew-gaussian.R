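#' Skew-Gaussian fitness curve parameters
#'
#' Parameter set for a skew-normal shaped fitness curve
#' \eqn{f(z) = (2/\omega)\,\phi((z-\xi)/\omega)\,\Phi(\alpha (z-\xi)/\omega)},
#' where \eqn{\phi} and \eqn{\Phi} are the standard normal density and CDF.
#' Skewed curves of this family are used to describe fitness as a function of
#' a bounded phenotype under moderate vs. extreme conditions: the phenotype
#' that does best in one environment does poorly in the other.
#'
#' @param location Location parameter \eqn{\xi} (phenotype units).
#' @param scale Scale parameter \eqn{\omega}; must be strictly positive.
#' @param skew Slant parameter \eqn{\alpha} (dimensionless); 0 gives a plain
#'   Gaussian curve.
#' @return An object of class `skew_gaussian_params`.
#' @examples
#' moderate <- skew_gaussian_params(0.1, 0.3, 5)
#' skew_gaussian_fitness(0.1, moderate)
#' @export
skew_gaussian_params <- function(location, scale, skew) {
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location)) {
    stop("`location` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(skew) || length(skew) != 1L || !is.finite(skew)) {
    stop("`skew` must be a single finite number", call. = FALSE)
  }
  structure(
    list(location = location, scale = scale, skew = skew),
    class = "skew_gaussian_params"
  )
}

#' Evaluate a skew-Gaussian fitness curve
#'
#' @param z Phenotype value(s); any finite real.
#' @param params A [skew_gaussian_params()] object.
#' @return Non-negative fitness value(s), same length as `z`.
#' @export
skew_gaussian_fitness <- function(z, params) {
  if (!inherits(params, "skew_gaussian_params")) {
    params <- do.call(skew_gaussian_params, as.list(params))
  }
  u <- (z - params$location) / params$scale
  (2 / params$scale) * stats::dnorm(u) * stats::pnorm(params$skew * u)
}
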