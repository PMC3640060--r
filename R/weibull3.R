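# Three-parameter Weibull: the standard baseline for diameter distributions.
# Thin shifted wrappers around the stats two-parameter Weibull; the CDF is
# defined as exactly 0 at and below the location so least-squares objectives
# stay defined when the location exceeds low class boundaries.

check_weibull3_params <- function(location, scale, shape) {
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location) || location < 0)
    stop("Weibull location 'a' must be a single finite value >= 0", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("Weibull scale 'b' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("Weibull shape 'c' must be a single finite value > 0", call. = FALSE)
  invisible(NULL)
}

#' The three-parameter Weibull distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the three-parameter Weibull with location \eqn{a \ge 0} (cm), scale
#' \eqn{b > 0} (cm) and shape \eqn{c > 0}:
#' \deqn{F(x) = 1 - \exp\{-((x-a)/b)^c\}, \quad x > a,}
#' and \eqn{F(x) = 0} for \eqn{x \le a}. The location must not exceed the
#' smallest diameter at which the model is evaluated for the fit to be
#' meaningful, the constraint that makes three-parameter Weibull fits hard to
#' converge and motivates the R distribution.
#'
#' @param x vector of quantiles (diameters, cm).
#' @param prob vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param location location parameter \eqn{a}, cm.
#' @param scale scale parameter \eqn{b}, cm.
#' @param shape shape parameter \eqn{c}, dimensionless.
#' @param log logical; return log-density?
#' @return `dweibull3` the density, `pweibull3` the CDF, `qweibull3` the
#'   quantile function, `rweibull3` random deviates.
#' @export
dweibull3 <- function(x, location, scale, shape, log = FALSE) {
  check_weibull3_params(location, scale, shape)
  out <- stats::dweibull(pmax(x - location, 0), shape = shape, scale = scale, log = log)
  out[x <= location] <- if (log) -Inf else 0
  out
}

#' @rdname dweibull3
#' @export
pweibull3 <- function(x, location, scale, shape) {
  check_weibull3_params(location, scale, shape)
  ifelse(x <= location, 0,
         stats::pweibull(x - location, shape = shape, scale = scale))
}

#' @rdname dweibull3
#' @export
qweibull3 <- function(prob, location, scale, shape) {
  check_weibull3_params(location, scale, shape)
  if (any(!is.finite(prob)) || any(prob <= 0) || any(prob >= 1))
    stop("'prob' must lie strictly inside (0, 1)", call. = FALSE)
  location + stats::qweibull(prob, shape = shape, scale = scale)
}

#' @rdname dweibull3
#' @export
rweibull3 <- function(n, location, scale, shape) {
  check_weibull3_params(location, scale, shape)
  location + stats::rweibull(n, shape = shape, scale = scale)
}

#' Inflection point of the three-parameter Weibull CDF
#'
#' For shape \eqn{c > 1} the CDF has an interior inflection at abscissa
#' \eqn{a + b((c-1)/c)^{1/c}} with ordinate \eqn{1 - e^{-(c-1)/c}}; for
#' \eqn{c \le 1} the CDF is concave on its support and no interior inflection
#' exists.
#'
#' @inheritParams dweibull3
#' @return list with `abscissa` (cm), `ordinate`, and `interior` (logical;
#'   `FALSE` with `NA` coordinates when `shape <= 1`).
#' @export
weibull3_inflection <- function(location, scale, shape) {
  check_weibull3_params(location, scale, shape)
  if (shape <= 1)
    return(list(abscissa = NA_real_, ordinate = NA_real_, interior = FALSE))
  w <- (shape - 1) / shape
  list(abscissa = location + scale * w^(1 / shape),
       ordinate = 1 - exp(-w),
       interior = TRUE)
}
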