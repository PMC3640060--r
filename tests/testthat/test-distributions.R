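# Closed-form mathematics of the R distribution, its Richards prototype, and
# the three-parameter Weibull.

test_that("R distribution CDF has the right landmarks and limits", {
  expect_equal(prdist(9.4, 1.26, 9.4, -1), 0.5)           # logistic midpoint
  expect_equal(prdist(1e6, 1.26, 9.4, -2), 1.0)           # upper asymptote
  expect_equal(prdist(-1e6, 1.26, 9.4, -2), 0.0)          # lower asymptote
  # at the inflection abscissa q + p ln(-r) the ordinate is (1 - 1/r)^r
  expect_equal(prdist(9.4 + 1.26 * log(3), 1.26, 9.4, -3), 27 / 64,
               tolerance = 1e-12)
  # strictly increasing
  x <- seq(2, 20, 0.25)
  expect_true(all(diff(prdist(x, 1.26, 9.4, -2)) > 0))
})

test_that("r = -1 reduces exactly to the logistic CDF", {
  x <- seq(-5, 25, length.out = 101)
  expect_equal(prdist(x, 1.7, 8.2, -1), stats::plogis((x - 8.2) / 1.7),
               tolerance = 1e-12)
})

test_that("R density is the derivative of the CDF, normalised, maximal at the inflection", {
  expect_equal(stats::integrate(drdist, -Inf, Inf, p = 1.26, q = 9.4,
                                r = -2)$value, 1, tolerance = 1e-6)
  # central difference of the CDF at x = 10
  h <- 1e-5
  fd <- (prdist(10 + h, 1.26, 9.4, -2) - prdist(10 - h, 1.26, 9.4, -2)) / (2 * h)
  expect_equal(drdist(10, 1.26, 9.4, -2), fd, tolerance = 1e-6)
  # mode of the density sits at the CDF inflection abscissa
  infl <- rdist_inflection(1.26, 9.4, -2)
  mode <- stats::optimize(drdist, c(2, 20), p = 1.26, q = 9.4, r = -2,
                          maximum = TRUE)$maximum
  expect_equal(mode, infl$abscissa, tolerance = 1e-5)
  expect_true(all(drdist(seq(-10, 30, 0.5), 1.26, 9.4, -2) >= 0))
})

test_that("R quantile inverts the CDF", {
  expect_equal(qrdist(0.5, 2, 7.5, -1), 7.5)  # logistic median is q
  expect_equal(qrdist(0.9, 1, 10, -1), 10 - log(1 / 0.9 - 1), tolerance = 1e-12)
  for (u in c(0.001, 0.333, 0.5, 0.9, 0.999))
    expect_equal(prdist(qrdist(u, 1.26, 9.4, -2), 1.26, 9.4, -2), u,
                 tolerance = 1e-10)
})

test_that("R inflection point matches a numeric second-derivative root and moves with r", {
  i1 <- rdist_inflection(1.26, 9.4, -1)
  expect_equal(i1$abscissa, 9.4)
  expect_equal(i1$ordinate, 0.5)
  i3 <- rdist_inflection(1.26, 9.4, -3)
  expect_equal(i3$abscissa, 9.4 + 1.26 * log(3), tolerance = 1e-12)
  expect_equal(i3$ordinate, 0.421875)
  num <- numeric_inflection_abscissa(function(x) prdist(x, 1.26, 9.4, -3),
                                     qrdist(0.05, 1.26, 9.4, -3),
                                     qrdist(0.95, 1.26, 9.4, -3))
  expect_equal(i3$abscissa, num, tolerance = 1e-6)
  # ordinate decreases monotonically as r decreases from -0.3 to -10
  rg <- seq(-0.3, -10, length.out = 60)
  ords <- vapply(rg, function(r) rdist_inflection(1, 5, r)$ordinate, 0)
  expect_true(all(diff(ords) < 0))
  expect_true(all(ords > 0 & ords < 1))
})

test_that("Richards prototype maps onto the R distribution exactly", {
  pr <- richards_to_rdist(B = -exp(1), k = 1, m = 2)
  expect_equal(unlist(pr), c(p = 1, q = 1, r = -1), tolerance = 1e-14)
  # CDF equality on a grid for a generic prototype
  B <- -4.7; k <- 0.81; m <- 1.6
  pr <- richards_to_rdist(B, k, m)
  x <- seq(-3, 20, length.out = 81)
  proto <- (1 - B * exp(-k * x))^(1 / (1 - m))
  expect_equal(prdist(x, pr$p, pr$q, pr$r), proto, tolerance = 1e-12)
  # B < -3 implies q > 0
  expect_gt(richards_to_rdist(-3.01, 2, 1.5)$q, 0)
  # m -> 1+ sends r -> -Inf
  expect_lt(richards_to_rdist(-4, 1, 1 + 1e-9)$r, -1e8)
  expect_error(richards_to_rdist(0.5, 1, 2), "negative")
  expect_error(richards_to_rdist(-4, 1, 0.9), "exceed 1")
  expect_error(richards_to_rdist(-4, -1, 2), "positive")
  expect_error(richards_to_rdist(-4, 1, 2, A = 0.9), "asymptote")
})

test_that("parameter-domain violations error at once", {
  expect_error(prdist(5, -1, 9, -2), "scale")
  expect_error(prdist(5, 1, -9, -2), "location")
  expect_error(prdist(5, 1, 9, 2), "shape")
  expect_error(qrdist(1.2, 1, 9, -2), "\\(0, 1\\)")
  expect_error(pweibull3(5, 1, -2, 2), "scale")
  expect_error(pweibull3(5, 1, 2, -2), "shape")
  expect_error(pweibull3(5, -1, 2, 2), "location")
})

test_that("three-parameter Weibull CDF, quantile and density behave", {
  expect_equal(pweibull3(3, 3, 5, 2), 0)       # support boundary
  expect_equal(pweibull3(1, 3, 5, 2), 0)       # below the location
  expect_equal(pweibull3(log(2), 0, 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(pweibull3(8, 3, 5, 2), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(qweibull3(0.5, 0, 1, 1), log(2), tolerance = 1e-12)
  expect_equal(qweibull3(0.5, 2, 3, 1.7), 2 + 3 * log(2)^(1 / 1.7),
               tolerance = 1e-12)
  expect_equal(stats::integrate(dweibull3, 1, Inf, location = 1, scale = 4.53,
                                shape = 1.93)$value, 1, tolerance = 1e-6)
  for (u in c(0.001, 0.333, 0.5, 0.9, 0.999))
    expect_equal(pweibull3(qweibull3(u, 1, 5, 2), 1, 5, 2), u,
                 tolerance = 1e-10)
})

test_that("Weibull inflection point exists iff shape > 1 and matches numerics", {
  wi <- weibull3_inflection(0, 1, 2)
  expect_true(wi$interior)
  expect_equal(wi$abscissa, sqrt(0.5), tolerance = 1e-12)
  expect_equal(wi$ordinate, 1 - exp(-0.5), tolerance = 1e-12)
  num <- numeric_inflection_abscissa(function(x) pweibull3(x, 0, 1, 2),
                                     0.1, qweibull3(0.95, 0, 1, 2))
  expect_equal(wi$abscissa, num, tolerance = 1e-6)
  expect_false(weibull3_inflection(0, 1, 1)$interior)
  expect_false(weibull3_inflection(2, 3, 0.7)$interior)
  # ordinate tends to 1 - 1/e as the shape grows
  expect_equal(weibull3_inflection(0, 1, 1e6)$ordinate, 1 - exp(-1),
               tolerance = 1e-5)
})

test_that("density/CDF consistency and inflection oracle hold over random parameter draws", {
  set.seed(401)
  for (i in 1:50) {
    pr <- random_rdist_params()
    p <- pr[["p"]]; q <- pr[["q"]]; r <- pr[["r"]]
    cdf <- function(x) prdist(x, p, q, r)
    grid <- seq(qrdist(0.005, p, q, r), qrdist(0.995, p, q, r),
                length.out = 200)
    h <- 1e-5
    expect_equal((cdf(grid + h) - cdf(grid - h)) / (2 * h),
                 drdist(grid, p, q, r), tolerance = 1e-6)
    ana <- unname(rdist_inflection(p, q, r)$abscissa)
    num <- numeric_inflection_abscissa(cdf, grid[1], grid[200])
    expect_equal(ana, num, tolerance = 1e-6)
  }
  for (i in 1:50) {
    pw <- random_weibull3_params(shape_gt_1 = TRUE)
    a <- pw[["a"]]; b <- pw[["b"]]; cc <- pw[["c"]]
    cdf <- function(x) pweibull3(x, a, b, cc)
    grid <- seq(qweibull3(0.005, a, b, cc), qweibull3(0.995, a, b, cc),
                length.out = 200)
    h <- 1e-5
    expect_equal((cdf(grid + h) - cdf(grid - h)) / (2 * h),
                 dweibull3(grid, a, b, cc), tolerance = 1e-6)
    ana <- unname(weibull3_inflection(a, b, cc)$abscissa)
    num <- numeric_inflection_abscissa(cdf, max(grid[1], a + 1e-3),
                                       grid[200])
    expect_equal(ana, num, tolerance = 1e-6)
  }
})
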