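# Diameter-class machinery. Classes are fixed-width bins on an absolute
# scale anchored at a lower bound of 1 cm: with the default 2-cm width,
# diameters in [1, 3) fall in class k = 2, [3, 5) in k = 4, and so on, the
# class index being the midpoint of the interval. Measurements recorded to
# 0.1 cm ("1-2.9 cm") are covered by the half-open convention.

#' Assign diameters to diameter classes
#'
#' @param d vector of diameters at breast height, cm.
#' @param width class width, cm (default 2).
#' @param lower lower bound of the first class, cm (default 1).
#' @return vector of class midpoints (even integers under the defaults).
#' @examples
#' dbh_class(c(1, 2.9, 3))  # 2 2 4
#' @export
dbh_class <- function(d, width = 2, lower = 1) {
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("diameters must be finite numbers", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a single positive number", call. = FALSE)
  if (any(d < lower))
    stop(sprintf("diameter %.3g cm lies below the first class lower bound (%g cm)",
                 min(d), lower), call. = FALSE)
  lower + width / 2 + width * floor((d - lower) / width)
}

#' Build a diameter-class histogram for one stand
#'
#' Computes per-class counts, relative frequencies f_k = n_k / N and
#' cumulative frequencies F_k over fixed-width classes. Empty classes interior
#' to the occupied range are retained with zero count so the cumulative curve
#' is defined on a regular grid of midpoints.
#'
#' @inheritParams dbh_class
#' @param diameters vector of tree diameters, cm (at least one tree).
#' @return a `dd_histogram`: a data frame with columns `midpoint`, `count`,
#'   `frequency`, `cumulative`, and attributes `n_total`, `width`, `lower`.
#' @export
diameter_histogram <- function(diameters, width = 2, lower = 1) {
  if (length(diameters) < 1L)
    stop("cannot build a histogram from an empty tree list", call. = FALSE)
  mids <- dbh_class(diameters, width = width, lower = lower)
  grid <- seq(min(mids), max(mids), by = width)
  counts <- as.vector(table(factor(mids, levels = grid)))
  n <- length(diameters)
  freq <- counts / n
  out <- data.frame(midpoint = grid, count = counts,
                    frequency = freq, cumulative = cumsum(freq))
  attr(out, "n_total") <- n
  attr(out, "width") <- width
  attr(out, "lower") <- lower
  class(out) <- c("dd_histogram", "data.frame")
  out
}

#' @export
print.dd_histogram <- function(x, ...) {
  cat(sprintf("Diameter-class histogram: %d trees, %d classes of %g cm\n",
              attr(x, "n_total"), nrow(x), attr(x, "width")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# class boundaries of a histogram
hist_upper <- function(hist) hist$midpoint + attr(hist, "width") / 2
hist_lower <- function(hist) hist$midpoint - attr(hist, "width") / 2

# empirical quantiles by linear interpolation of the cumulative curve through
# (lower bound of first occupied class, 0) and the class upper boundaries
hist_quantile <- function(hist, probs) {
  up <- hist_upper(hist)
  x0 <- min(hist_lower(hist))
  xs <- c(x0, up)
  Fs <- c(0, hist$cumulative)
  keep <- !duplicated(Fs)
  stats::approx(Fs[keep], xs[keep], xout = probs, rule = 2)$y
}

#' Quadratic mean diameter
#'
#' \eqn{D_g = \sqrt{\sum d_i^2 / n}}: the diameter of the tree of mean basal
#' area, always at least the arithmetic mean diameter.
#'
#' @param diameters vector of tree diameters, cm.
#' @return quadratic mean DBH, cm.
#' @export
quadratic_mean_dbh <- function(diameters) {
  if (length(diameters) < 1L)
    stop("cannot compute quadratic mean DBH of an empty tree list", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("diameters must be finite and positive", call. = FALSE)
  sqrt(mean(diameters^2))
}

binned_moments <- function(hist) {
  f <- hist$frequency
  x <- hist$midpoint
  xb <- sum(f * x)
  s2 <- sum(f * (x - xb)^2)
  if (s2 <= 0)
    stop("binned shape statistics need at least two occupied classes", call. = FALSE)
  list(mean = xb, s = sqrt(s2))
}

#' Binned skewness and kurtosis of a diameter distribution
#'
#' Frequency-weighted third and fourth central moments of the class midpoints,
#' scaled by the frequency-weighted standard deviation cubed and to the
#' fourth. Kurtosis is reported raw (the normal distribution has kurtosis 3);
#' set `excess = TRUE` to subtract 3.
#'
#' @param hist a `dd_histogram`.
#' @param excess logical; subtract 3 from the kurtosis?
#' @return a single numeric value.
#' @export
binned_skewness <- function(hist) {
  m <- binned_moments(hist)
  sum(hist$frequency * (hist$midpoint - m$mean)^3) / m$s^3
}

#' @rdname binned_skewness
#' @export
binned_kurtosis <- function(hist, excess = FALSE) {
  m <- binned_moments(hist)
  k <- sum(hist$frequency * (hist$midpoint - m$mean)^4) / m$s^4
  if (excess) k - 3 else k
}
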