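# Stepwise prediction equations (PPM) and parameter recovery (PRM).

make_ppm_cohort <- function(n = 60) {
  age <- stats::runif(n, 6, 20)
  dg <- 15.3 * age^0.7 * 5000^-0.258 * exp(stats::rnorm(n, 0, 0.05))
  data.frame(stand_id = sprintf("S%03d", seq_len(n)), age = age, dg = dg,
             planting_density = 5000, site_index = stats::rnorm(n, 14.5, 1),
             mean_height = 0.6 * age, dominant_height = 0.7 * age)
}

test_that("stepwise regression recovers a quadratic generating structure", {
  set.seed(413)
  df <- make_ppm_cohort()
  df$p <- 0.5 + 0.06 * df$age + 0.002 * df$age^2 + stats::rnorm(60, 0, 0.08)
  eq <- fit_ppm_equation(df, "p", "age")
  expect_true(all(c("age", "I(age^2)") %in% eq$terms))
  expect_gt(eq$r_squared, 0.7)

  df$xstar <- 1.5 + 0.9 * df$dg + 0.004 * df$dg^2 + stats::rnorm(60, 0, 0.15)
  eqx <- fit_ppm_equation(df, "xstar", "dg")
  expect_gt(eqx$r_squared, 0.9)
  # prediction reproduces the fitted values
  pred <- predict(eqx, df)
  expect_equal(length(pred), 60)
  expect_gt(stats::cor(pred, df$xstar), 0.94)
})

test_that("stepwise regression tolerates uninformative responses and validates inputs", {
  set.seed(414)
  df <- make_ppm_cohort()
  df$y <- stats::rnorm(60)
  eq <- fit_ppm_equation(df, "y", c("age", "dg"))
  expect_s3_class(eq, "prediction_equation")
  expect_lt(eq$r_squared, 0.3)
  expect_error(fit_ppm_equation(df[1:5, ], "y", "age"), "at least 10")
  expect_error(fit_ppm_equation(df, "nope", "age"), "not in data")
  # perfectly collinear candidates are dropped, not fatal
  df$dup <- df$age
  expect_s3_class(suppressWarnings(fit_ppm_equation(df, "y", c("age", "dup"))),
                  "prediction_equation")
})

test_that("shape recovery from the inflection abscissa is the exact algebraic inverse", {
  expect_equal(recover_r_from_inflection(1.3, 9.4, 9.4), -1)
  expect_equal(recover_r_from_inflection(1.26, 9.4, 10.784), -3,
               tolerance = 1e-3)
  set.seed(415)
  for (i in 1:100) {
    pr <- random_rdist_params()
    xs <- rdist_inflection(pr[["p"]], pr[["q"]], pr[["r"]])$abscissa
    expect_equal(recover_r_from_inflection(pr[["p"]], pr[["q"]], xs),
                 pr[["r"]], tolerance = 1e-10)
    expect_lt(recover_r_from_inflection(pr[["p"]], pr[["q"]],
                                        stats::runif(1, 0, 30)), 0)
  }
})

test_that("full percentile recovery inverts the forward map", {
  fw <- function(p, q, r) c(qrdist(0.333, p, q, r), qrdist(0.9, p, q, r),
                            rdist_inflection(p, q, r)$abscissa)
  v <- fw(1.26, 9.4, -2)
  rec <- recover_rdist_from_percentiles(v[1], v[2], v[3])
  expect_equal(c(rec$p, rec$q, rec$r), c(1.26, 9.4, -2), tolerance = 1e-6)
  # logistic case: closed-form percentiles round trip exactly
  v1 <- fw(2, 12, -1)
  rec1 <- recover_rdist_from_percentiles(v1[1], v1[2], v1[3])
  expect_equal(c(rec1$p, rec1$q, rec1$r), c(2, 12, -1), tolerance = 1e-8)
  set.seed(416)
  for (i in 1:100) {
    pr <- random_rdist_params()
    v <- fw(pr[["p"]], pr[["q"]], pr[["r"]])
    rec <- recover_rdist_from_percentiles(v[1], v[2], v[3])
    expect_equal(c(rec$p, rec$q, rec$r), unname(pr), tolerance = 1e-6)
  }
  expect_error(recover_rdist_from_percentiles(10, 9, 9.5), "d333 < d900")
  expect_error(recover_rdist_from_percentiles(9, 9.05, 2), "no R distribution")
})

test_that("Weibull scale recovery from the median is exact", {
  expect_equal(recover_weibull_b(0, 1, log(2)), 1, tolerance = 1e-12)
  expect_equal(recover_weibull_b(3, 2, 3 + sqrt(log(2))), 1, tolerance = 1e-12)
  set.seed(417)
  for (i in 1:100) {
    pw <- random_weibull3_params()
    d50 <- qweibull3(0.5, pw[["a"]], pw[["b"]], pw[["c"]])
    b <- recover_weibull_b(pw[["a"]], pw[["c"]], d50)
    expect_equal(b, pw[["b"]], tolerance = 1e-10)
    expect_equal(qweibull3(0.5, pw[["a"]], b, pw[["c"]]), d50,
                 tolerance = 1e-10)
  }
  expect_error(recover_weibull_b(5, 2, 4.9), "exceed")
})

test_that("method codes wire the right equations, characteristics and recovery paths", {
  set.seed(418)
  co <- generate_cohorts(cohort_design(), seed = 3)
  fitting <- co$fitting[seq(1, 150, 5)]    # 30 stands keep this test quick
  stab <- as_stand_table(fitting)
  rfits <- fit_stands(fitting, "rdist", "nrm")
  wfits <- fit_stands(fitting, "weibull3", "nrm")

  mA <- build_ppm_models("A", rfits, stab)
  expect_setequal(names(mA$equations), c("p", "q", "xstar"))
  expect_setequal(mA$required_characteristics, c("age", "dg"))

  mC <- build_ppm_models("C", rfits, stab)
  expect_equal(mC$required_characteristics, "dg")
  # Method C predicts from a table holding only stand_id and Dg
  slim <- data.frame(stand_id = c("X1", "X2"), dg = c(8, 13))
  pC <- predict_stand_distribution(mC, slim)
  expect_equal(pC$family, c("rdist", "rdist"))
  expect_true(all(pC$r < 0) && all(pC$p > 0) && all(pC$q > 0))

  mB <- build_ppm_models("B", rfits, stab)
  expect_length(mB$required_characteristics, 6)
  noDom <- stab[, setdiff(names(stab), "dominant_height")]
  expect_error(predict_stand_distribution(mB, noDom), "dominant_height")

  mD <- build_ppm_models("D", wfits, stab)
  expect_length(mD$required_characteristics, 6)
  pD <- predict_stand_distribution(mD, stab)
  expect_true(all(pD$b > 0) && all(pD$c > 0) && all(pD$a >= 0))

  # family/method mismatches are rejected
  expect_error(build_ppm_models("A", wfits, stab), "rdist")
  expect_error(build_ppm_models("E", wfits, stab), "MLEM")
  expect_error(build_ppm_models("Z", rfits, stab), "unknown method")
})

test_that("predictions recover generating CDFs when parameters follow known quadratic links", {
  set.seed(419)
  # one planting density, so every link is a smooth function of age and Dg
  grid <- expand.grid(age = c(6:10, seq(12, 20, 2)), density = 5000,
                      rep = 1:15)
  dg0 <- 15.3 * grid$age^0.7 * grid$density^-0.258
  n <- nrow(grid)
  gen <- data.frame(
    p = 0.55 + 0.05 * grid$age + 0.001 * grid$age^2 + stats::rnorm(n, 0, 0.02),
    q = -0.5 + 0.98 * dg0 + stats::rnorm(n, 0, 0.08),
    r = -exp(-0.591 + 0.0505 * grid$age + stats::rnorm(n, 0, 0.04)))
  stands <- lapply(seq_len(n), function(i) {
    u <- stats::runif(300, prdist(1, gen$p[i], gen$q[i], gen$r[i]), 1 - 1e-9)
    stand_record(sprintf("L%03d", i),
                 qrdist(u, gen$p[i], gen$q[i], gen$r[i]),
                 age = grid$age[i])
  })
  stab <- data.frame(stand_id = sprintf("L%03d", seq_len(n)),
                     age = grid$age, dg = dg0,
                     planting_density = grid$density,
                     site_index = stats::rnorm(n, 14.5, 1),
                     mean_height = 0.6 * grid$age + stats::rnorm(n, 0, 0.3),
                     dominant_height = 0.7 * grid$age + stats::rnorm(n, 0, 0.3))
  rfits <- fit_stands(stands, "rdist", "nrm")
  for (m in c("A", "B", "C")) {
    mod <- suppressWarnings(build_ppm_models(m, rfits, stab))
    pred <- predict_stand_distribution(mod, stab)
    sup <- vapply(seq_len(n), function(i) {
      x <- seq(qrdist(0.01, gen$p[i], gen$q[i], gen$r[i]),
               qrdist(0.99, gen$p[i], gen$q[i], gen$r[i]), length.out = 100)
      max(abs(prdist(x, pred$p[i], pred$q[i], pred$r[i]) -
              prdist(x, gen$p[i], gen$q[i], gen$r[i])))
    }, 0)
    expect_gt(mean(sup < 0.05), 0.9)
  }
})

test_that("prediction-equation sets survive serialization", {
  set.seed(420)
  co <- generate_cohorts(cohort_design(), seed = 7)
  fitting <- co$fitting[seq(1, 150, 5)]
  stab <- as_stand_table(fitting)
  mA <- build_ppm_models("A", fit_stands(fitting, "rdist", "nrm"), stab)
  tp <- tempfile(fileext = ".yml")
  write_ppm_models(mA, tp)
  back <- read_ppm_models(tp)
  expect_equal(back$method, "A")
  p1 <- predict_stand_distribution(mA, stab)
  p2 <- predict_stand_distribution(back, stab)
  expect_equal(p1, p2, tolerance = 1e-8)
})
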