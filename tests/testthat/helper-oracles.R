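# Shared numeric oracles, kept independent of the closed forms they check.

# abscissa of the CDF inflection as the root of a central-difference second
# derivative, searched between two quantiles of the distribution
numeric_inflection_abscissa <- function(cdf, lo, hi, h = 1e-3) {
  d2 <- function(x) (cdf(x + h) - 2 * cdf(x) + cdf(x - h)) / h^2
  stats::uniroot(d2, c(lo, hi), tol = 1e-10)$root
}

rel_err <- function(est, tru) abs(est - tru) / abs(tru)

# random admissible parameter draws spanning the empirically observed ranges
random_rdist_params <- function() {
  c(p = stats::runif(1, 0.5, 2.6),
    q = stats::runif(1, 3.4, 18.3),
    r = -exp(stats::runif(1, log(0.3), log(6.8))))
}

random_weibull3_params <- function(shape_gt_1 = FALSE) {
  c(a = stats::runif(1, 0, 8),
    b = stats::runif(1, 4.5, 17.6),
    c = stats::runif(1, if (shape_gt_1) 1.2 else 0.5, 8.6))
}

# R-distribution draws truncated below the class-system lower bound, so tree
# lists are always valid stand records
rrdist_trunc <- function(n, p, q, r, lo = 1) {
  qrdist(stats::runif(n, prdist(lo, p, q, r), 1 - 1e-12), p, q, r)
}

# histogram with exact model cumulative frequencies at class upper bounds
exact_histogram <- function(cdf, mids, width = 2, lower = 1) {
  Fk <- cdf(mids + width / 2)
  structure(data.frame(midpoint = mids, count = rep(1L, length(mids)),
                       frequency = rep(1 / length(mids), length(mids)),
                       cumulative = Fk),
            n_total = length(mids), width = width, lower = lower,
            class = c("dd_histogram", "data.frame"))
}
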