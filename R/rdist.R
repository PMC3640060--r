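# The R distribution: a sigmoid CDF obtained by rewriting the Richards growth
# curve y = A (1 - B e^{-k x})^{1/(1-m)} (A = 1, B < 0, k > 0, m > 1) in terms
# of a scale p = 1/k, a location q = ln(-B)/k and a shape r = 1/(1-m):
#
#   F(x) = (1 + e^{-(x-q)/p})^r,   p > 0, q > 0, r < 0.
#
# At r = -1 this is the logistic CDF; more negative r skews the curve and
# moves the inflection ordinate (1 - 1/r)^r below one half.

# log(1 + exp(t)) without overflow/underflow
log1pexp <- function(t) {
  out <- t
  lo <- t <= -37
  md <- t > -37 & t <= 18
  hi <- t > 18 & t <= 33.3
  out[lo] <- exp(t[lo])
  out[md] <- log1p(exp(t[md]))
  out[hi] <- t[hi] + exp(-t[hi])
  out
}

check_rdist_params <- function(p, q, r) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("R distribution scale 'p' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    stop("R distribution location 'q' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r >= 0)
    stop("R distribution shape 'r' must be a single finite value < 0", call. = FALSE)
  invisible(NULL)
}

#' The R distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the R distribution, a Richards-function reparameterisation used as a
#' cumulative diameter distribution model for even-aged stands:
#' \deqn{F(x) = \left(1 + e^{-(x-q)/p}\right)^{r}}
#' with scale \eqn{p > 0} (cm), location \eqn{q > 0} (cm) and dimensionless
#' shape \eqn{r < 0}. For \eqn{r = -1} the R distribution reduces to the
#' logistic distribution with location \eqn{q} and scale \eqn{p}. Unlike the
#' three-parameter Weibull, its support is the whole real line, so the
#' location parameter is unconstrained by the smallest observed diameter --
#' the property that makes its nonlinear fits converge easily.
#'
#' @param x vector of quantiles (diameters, cm).
#' @param prob vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param p scale parameter, cm (> 0).
#' @param q location parameter, cm (> 0).
#' @param r shape parameter, dimensionless (< 0).
#' @param log logical; return log-density?
#' @return `drdist` the density, `prdist` the CDF, `qrdist` the quantile
#'   function, `rrdist` random deviates.
#' @examples
#' prdist(9.4, p = 1.26, q = 9.4, r = -1)   # 0.5: logistic midpoint
#' qrdist(0.5, p = 1.26, q = 9.4, r = -1)   # the location q
#' @export
drdist <- function(x, p, q, r, log = FALSE) {
  check_rdist_params(p, q, r)
  z <- (x - q) / p
  lf <- log(-r) - log(p) - z + (r - 1) * log1pexp(-z)
  if (log) lf else exp(lf)
}

#' @rdname drdist
#' @export
prdist <- function(x, p, q, r) {
  check_rdist_params(p, q, r)
  z <- (x - q) / p
  exp(r * log1pexp(-z))
}

#' @rdname drdist
#' @export
qrdist <- function(prob, p, q, r) {
  check_rdist_params(p, q, r)
  if (any(!is.finite(prob)) || any(prob <= 0) || any(prob >= 1))
    stop("'prob' must lie strictly inside (0, 1)", call. = FALSE)
  # invert u = (1 + e^{-z})^r:  e^{-z} = u^{1/r} - 1 computed as expm1(log(u)/r)
  q - p * log(expm1(log(prob) / r))
}

#' @rdname drdist
#' @export
rrdist <- function(n, p, q, r) {
  qrdist(stats::runif(n), p, q, r)
}

#' Inflection point of the R distribution CDF
#'
#' The cumulative curve changes concavity at abscissa \eqn{x^* = q + p
#' \ln(-r)} with ordinate \eqn{(1 - 1/r)^r}, which depends on the shape
#' parameter alone. The ordinate equals 0.5 at \eqn{r = -1} and decreases as
#' \eqn{r} decreases.
#'
#' @inheritParams drdist
#' @return list with elements `abscissa` (cm) and `ordinate` (in (0, 1)).
#' @export
rdist_inflection <- function(p, q, r) {
  check_rdist_params(p, q, r)
  list(abscissa = q + p * log(-r), ordinate = (1 - 1 / r)^r)
}

#' Convert Richards prototype parameters to R distribution parameters
#'
#' The Richards sigmoid \eqn{y = A (1 - B e^{-kx})^{1/(1-m)}} fitted to a
#' cumulative diameter distribution has \eqn{A = 1}, \eqn{B < 0},
#' \eqn{k > 0} and \eqn{m > 1}; empirically \eqn{B < -3}, which guarantees a
#' positive location. The equivalent R distribution parameters are
#' \eqn{p = 1/k}, \eqn{q = \ln(-B)/k}, \eqn{r = 1/(1-m)}.
#'
#' @param B initial-state coefficient (< 0; must be < -1 for q > 0).
#' @param k rate parameter, 1/cm (> 0).
#' @param m allometric shape parameter (> 1).
#' @param A asymptote; must be 1 for a CDF.
#' @return list with elements `p`, `q`, `r`.
#' @export
richards_to_rdist <- function(B, k, m, A = 1) {
  if (!isTRUE(all.equal(A, 1)))
    stop("a cumulative distribution requires asymptote A = 1", call. = FALSE)
  if (!is.finite(B) || B >= 0)
    stop("Richards 'B' must be negative for a diameter CDF", call. = FALSE)
  if (!is.finite(k) || k <= 0)
    stop("Richards rate 'k' must be positive", call. = FALSE)
  if (!is.finite(m) || m <= 1)
    stop("Richards shape 'm' must exceed 1 for a diameter CDF", call. = FALSE)
  out <- list(p = 1 / k, q = log(-B) / k, r = 1 / (1 - m))
  check_rdist_params(out$p, out$q, out$r)
  out
}
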