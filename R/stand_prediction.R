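# Stand-level prediction: PPM regresses fitted distribution parameters,
# percentile diameters and the inflection abscissa on stand characteristics
# (stepwise second-degree polynomials, significance-to-enter and -to-stay
# 0.5); PRM recovers distribution parameters from those predicted landmarks.
#
# The five method codes compose the two ideas:
#   A  R distribution, PPM + PRM: p ~ age, q ~ Dg, x* ~ Dg, r recovered
#      from the inflection abscissa (2 characteristics).
#   B  R distribution, PPM + PRM: p and q stepwise over six characteristics,
#      x* ~ Dg, r recovered (6 characteristics).
#   C  R distribution, pure PRM: D_0.333, D_0.9 and x* each ~ Dg, all three
#      parameters recovered from the percentiles (1 characteristic).
#   D  Weibull (NRM fits): a and c stepwise over six characteristics,
#      D_0.5 stepwise, b recovered from the median (6 characteristics).
#   E  as D but trained on MLEM fits.

SIX_CHARACTERISTICS <- c("age", "planting_density", "site_index",
                         "mean_height", "dominant_height", "dg")

poly_terms <- function(vars) as.vector(rbind(vars, sprintf("I(%s^2)", vars)))

lm_on_terms <- function(data, response, terms) {
  fml <- stats::reformulate(if (length(terms)) terms else "1", response = response)
  stats::lm(fml, data = data)
}

term_pvalues <- function(fit) {
  sm <- summary(fit)$coefficients
  full <- coef(fit)[-1]  # drop intercept; aliased terms appear as NA
  pv <- rep(NA_real_, length(full))
  names(pv) <- names(full)
  hit <- intersect(rownames(sm), names(pv))
  pv[hit] <- sm[hit, "Pr(>|t|)"]
  pv
}

#' Fit one stepwise polynomial prediction equation
#'
#' Regresses a response (a fitted distribution parameter, a percentile
#' diameter or the inflection abscissa) on stand characteristics, selecting
#' among linear and quadratic terms by forward-backward stepwise regression
#' with significance level 0.5 both to enter and to stay. Collinear terms are
#' dropped with a warning.
#'
#' @param data data frame holding the response and the candidate
#'   characteristics, one row per stand (at least 10).
#' @param response name of the response column.
#' @param candidates character vector of candidate characteristic names.
#' @param alpha_enter,alpha_stay stepwise significance levels (default 0.5).
#' @return a `prediction_equation`: list with `response`, `terms`,
#'   `coefficients` (including the intercept), `r_squared`, `n`.
#' @export
fit_ppm_equation <- function(data, response, candidates,
                             alpha_enter = 0.5, alpha_stay = 0.5) {
  if (nrow(data) < 10L)
    stop("prediction equations need at least 10 stands", call. = FALSE)
  missing <- setdiff(c(response, candidates), names(data))
  if (length(missing))
    stop(sprintf("column(s) not in data: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  pool <- poly_terms(candidates)
  current <- character(0)
  for (pass in seq_len(4L * length(pool) + 4L)) {
    changed <- FALSE
    avail <- setdiff(pool, current)
    if (length(avail)) {
      pv <- vapply(avail, function(tm) {
        fit <- lm_on_terms(data, response, c(current, tm))
        p <- term_pvalues(fit)[tm]
        if (is.na(p)) Inf else p  # aliased with current terms: skip
      }, numeric(1))
      if (min(pv) < alpha_enter) {
        current <- c(current, avail[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(current)) {
      pv <- term_pvalues(lm_on_terms(data, response, current))
      if (anyNA(pv)) {
        warning("dropping collinear term(s): ",
                paste(names(pv)[is.na(pv)], collapse = ", "))
        current <- setdiff(current, names(pv)[is.na(pv)])
        changed <- TRUE
      } else if (max(pv) > alpha_stay) {
        current <- setdiff(current, names(pv)[which.max(pv)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- lm_on_terms(data, response, current)
  cf <- coef(fit)
  cf <- cf[!is.na(cf)]
  structure(list(response = response,
                 terms = setdiff(names(cf), "(Intercept)"),
                 coefficients = cf,
                 r_squared = summary(fit)$r.squared,
                 n = nrow(data)),
            class = "prediction_equation")
}

#' @export
print.prediction_equation <- function(x, ...) {
  rhs <- paste(sprintf("%+.4g*%s", x$coefficients[x$terms], x$terms),
               collapse = " ")
  cat(sprintf("%s = %.4g %s   (R2 = %.4f, n = %d)\n",
              x$response, x$coefficients[["(Intercept)"]], rhs,
              x$r_squared, x$n))
  invisible(x)
}

#' @export
predict.prediction_equation <- function(object, newdata, ...) {
  vals <- vapply(names(object$coefficients), function(tm) {
    if (tm == "(Intercept)") rep(1, nrow(newdata))
    else eval(parse(text = tm), envir = newdata)
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) vals <- matrix(vals, nrow = 1)
  as.vector(vals %*% object$coefficients)
}

#' Recover the R distribution shape from the inflection abscissa
#'
#' Inverts \eqn{x^* = q + p \ln(-r)}: \eqn{r = -\exp((x^* - q)/p)}, which is
#' negative for any input, so the recovered shape is always admissible.
#'
#' @param p,q R distribution scale and location, cm.
#' @param x_star inflection abscissa, cm.
#' @return shape parameter `r` (< 0).
#' @export
recover_r_from_inflection <- function(p, q, x_star) {
  if (!is.finite(p) || p <= 0) stop("'p' must be positive", call. = FALSE)
  -exp((x_star - q) / p)
}

#' Recover all R distribution parameters from two percentiles and the
#' inflection abscissa
#'
#' Solves \eqn{F(D_{0.333}) = 0.333}, \eqn{F(D_{0.9}) = 0.9} and
#' \eqn{x^* = q + p\ln(-r)} jointly. For a trial shape \eqn{r}, the two
#' percentile equations give closed forms
#' \eqn{p(r) = (D_{0.9}-D_{0.333}) / [\ln(0.333^{1/r}-1) - \ln(0.9^{1/r}-1)]}
#' and \eqn{q(r) = D_{0.333} + p(r)\ln(0.333^{1/r}-1)}, leaving a
#' one-dimensional root search in \eqn{r}. The bracket (-50, -0.01) covers
#' the empirical shape range with wide margin and is expanded geometrically
#' before declaring the triple infeasible.
#'
#' @param d333,d900 diameters at cumulative frequencies 0.333 and 0.9, cm
#'   (`d333 < d900`).
#' @param x_star inflection abscissa, cm.
#' @param bracket initial search interval for the shape.
#' @return list with `p`, `q`, `r` reproducing all three inputs.
#' @export
recover_rdist_from_percentiles <- function(d333, d900, x_star,
                                           bracket = c(-50, -0.01)) {
  if (!is.finite(d333) || !is.finite(d900) || d333 >= d900)
    stop("percentile diameters must satisfy d333 < d900", call. = FALSE)
  lnA <- function(r) log(expm1(log(0.333) / r))
  lnB <- function(r) log(expm1(log(0.9) / r))
  p_of <- function(r) (d900 - d333) / (lnA(r) - lnB(r))
  q_of <- function(r) d333 + p_of(r) * lnA(r)
  g <- function(r) q_of(r) + p_of(r) * log(-r) - x_star
  lo <- min(bracket); hi <- max(bracket)
  for (k in 0:6) {
    glo <- g(lo); ghi <- g(hi)
    if (is.finite(glo) && is.finite(ghi) && glo * ghi <= 0) {
      root <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
      p <- p_of(root); q <- q_of(root)
      if (!is.finite(p) || p <= 0 || !is.finite(q) || q <= 0) break
      return(list(p = p, q = q, r = root))
    }
    lo <- lo * 4
    hi <- hi / 4
  }
  stop(sprintf(paste("no R distribution reproduces the triple d333 = %.4g,",
                     "d900 = %.4g, x_star = %.4g"), d333, d900, x_star),
       call. = FALSE)
}

#' Recover the Weibull scale from the median
#'
#' Inverts the CDF at the 0.5 percentile (a point near the inflection of the
#' curve): \eqn{b = (D_{0.5} - a) / (\ln 2)^{1/c}}.
#'
#' @param location Weibull location \eqn{a}, cm.
#' @param shape Weibull shape \eqn{c} (> 0).
#' @param d50 median diameter, cm (`> location`).
#' @return scale parameter `b`, cm.
#' @export
recover_weibull_b <- function(location, shape, d50) {
  if (!is.finite(shape) || shape <= 0) stop("'shape' must be positive", call. = FALSE)
  if (!is.finite(d50) || d50 <= location)
    stop("median diameter must exceed the Weibull location", call. = FALSE)
  (d50 - location) / log(2)^(1 / shape)
}

method_spec <- function(method) {
  switch(method,
    A = list(family = "rdist", fit_method = "NRM",
             eqs = list(p = "age", q = "dg", xstar = "dg")),
    B = list(family = "rdist", fit_method = "NRM",
             eqs = list(p = SIX_CHARACTERISTICS, q = SIX_CHARACTERISTICS,
                        xstar = "dg")),
    C = list(family = "rdist", fit_method = "NRM",
             eqs = list(d333 = "dg", d900 = "dg", xstar = "dg")),
    D = list(family = "weibull3", fit_method = "NRM",
             eqs = list(a = SIX_CHARACTERISTICS, c = SIX_CHARACTERISTICS,
                        d50 = SIX_CHARACTERISTICS)),
    E = list(family = "weibull3", fit_method = "MLEM",
             eqs = list(a = SIX_CHARACTERISTICS, c = SIX_CHARACTERISTICS,
                        d50 = SIX_CHARACTERISTICS)),
    stop(sprintf("unknown method code '%s' (use A, B, C, D or E)", method),
         call. = FALSE))
}

#' Build the prediction-equation set for one method code
#'
#' Joins a per-stand fit table (from [fit_stands()]) with the stand
#' characteristics, derives the method's regression responses (parameters,
#' percentile diameters of the fitted curves, inflection abscissae) and fits
#' the stepwise prediction equations.
#'
#' @param method one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param fits per-stand fit table from [fit_stands()]; its `family` and
#'   `method` must match the method code (R-distribution NRM for A-C, Weibull
#'   NRM for D, Weibull MLEM for E).
#' @param stands stand-characteristics table ([as_stand_table()] or
#'   [read_stand_table()] plus a `dg` column).
#' @param alpha_enter,alpha_stay stepwise significance levels.
#' @return a `ppm_models` object.
#' @export
build_ppm_models <- function(method, fits, stands,
                             alpha_enter = 0.5, alpha_stay = 0.5) {
  spec <- method_spec(method)
  if (!all(fits$family == spec$family) || !all(fits$method == spec$fit_method))
    stop(sprintf("method %s needs %s fits obtained by %s", method,
                 spec$family, spec$fit_method), call. = FALSE)
  df <- merge(fits, stands, by = "stand_id")
  if (spec$family == "rdist") {
    df$xstar <- df$q + df$p * log(-df$r)
    df$d333 <- mapply(function(p, q, r) qrdist(0.333, p, q, r), df$p, df$q, df$r)
    df$d900 <- mapply(function(p, q, r) qrdist(0.9, p, q, r), df$p, df$q, df$r)
  } else {
    df$d50 <- mapply(function(a, b, cc) qweibull3(0.5, a, b, cc),
                     df$a, df$b, df$c)
  }
  equations <- lapply(names(spec$eqs), function(resp) {
    fit_ppm_equation(df, resp, spec$eqs[[resp]],
                     alpha_enter = alpha_enter, alpha_stay = alpha_stay)
  })
  names(equations) <- names(spec$eqs)
  structure(list(method = method, family = spec$family,
                 fit_method = spec$fit_method,
                 equations = equations,
                 required_characteristics = sort(unique(unlist(spec$eqs))),
                 n_stands = nrow(df)),
            class = "ppm_models")
}

#' @export
print.ppm_models <- function(x, ...) {
  cat(sprintf("Method %s (%s, %s fits; %d training stands)\n", x$method,
              x$family, x$fit_method, x$n_stands))
  cat(sprintf("  requires: %s\n",
              paste(x$required_characteristics, collapse = ", ")))
  for (eq in x$equations) { cat("  "); print(eq) }
  invisible(x)
}

clip_warn <- function(x, lo, hi, what) {
  if (x < lo || x > hi) {
    warning(sprintf("predicted %s = %.4g outside [%g, %g]; clipped", what, x, lo, hi))
    x <- min(max(x, lo), hi)
  }
  x
}

#' Predict the diameter distribution of unmeasured stands
#'
#' Applies a method's prediction equations to a table of stand
#' characteristics and completes the parameter set by the method's recovery
#' path (shape from the inflection abscissa for A and B, full percentile
#' recovery for C, scale from the median for D and E).
#'
#' @param models a `ppm_models` object from [build_ppm_models()].
#' @param stands stand-characteristics table containing every characteristic
#'   the method requires (see `models$required_characteristics`).
#' @return data frame with one row per stand: `stand_id`, `family` and the
#'   predicted parameters (`p`, `q`, `r` or `a`, `b`, `c`).
#' @export
predict_stand_distribution <- function(models, stands) {
  if (inherits(stands, "stand_record")) stands <- as_stand_table(stands)
  req <- models$required_characteristics
  missing <- setdiff(req, names(stands))
  if (length(missing))
    stop(sprintf("method %s requires missing stand characteristic(s): %s",
                 models$method, paste(missing, collapse = ", ")), call. = FALSE)
  bad <- req[vapply(req, function(v) anyNA(stands[[v]]), TRUE)]
  if (length(bad))
    stop(sprintf("method %s: stand characteristic(s) with missing values: %s",
                 models$method, paste(bad, collapse = ", ")), call. = FALSE)
  eqs <- models$equations
  pred <- lapply(eqs, predict, newdata = stands)
  rows <- lapply(seq_len(nrow(stands)), function(i) {
    if (models$method %in% c("A", "B")) {
      p <- clip_warn(pred$p[i], 0.05, 10, "p")
      q <- clip_warn(pred$q[i], 0.5, 50, "q")
      r <- recover_r_from_inflection(p, q, pred$xstar[i])
      data.frame(stand_id = stands$stand_id[i], family = "rdist",
                 p = p, q = q, r = r)
    } else if (models$method == "C") {
      pr <- recover_rdist_from_percentiles(pred$d333[i], pred$d900[i],
                                           pred$xstar[i])
      data.frame(stand_id = stands$stand_id[i], family = "rdist",
                 p = pr$p, q = pr$q, r = pr$r)
    } else {
      a <- max(pred$a[i], 0)
      cc <- clip_warn(pred$c[i], 0.2, 30, "c")
      b <- recover_weibull_b(a, cc, pred$d50[i])
      data.frame(stand_id = stands$stand_id[i], family = "weibull3",
                 a = a, b = b, c = cc)
    }
  })
  do.call(rbind, rows)
}

#' Serialize / restore a prediction-equation set
#'
#' Writes the method code, family and every equation (terms, coefficients,
#' R-squared) as structured key-value text.
#'
#' @param models a `ppm_models` object.
#' @param path file path.
#' @return `read_ppm_models` returns the restored `ppm_models`.
#' @export
write_ppm_models <- function(models, path) {
  obj <- list(method = models$method, family = models$family,
              fit_method = models$fit_method,
              n_stands = models$n_stands,
              required_characteristics = models$required_characteristics,
              equations = lapply(models$equations, function(eq)
                list(response = eq$response, r_squared = eq$r_squared,
                     n = eq$n, coefficients = as.list(eq$coefficients))))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_ppm_models
#' @export
read_ppm_models <- function(path) {
  obj <- yaml::read_yaml(path)
  equations <- lapply(obj$equations, function(eq) {
    cf <- unlist(eq$coefficients)
    structure(list(response = eq$response,
                   terms = setdiff(names(cf), "(Intercept)"),
                   coefficients = cf, r_squared = eq$r_squared, n = eq$n),
              class = "prediction_equation")
  })
  structure(list(method = obj$method, family = obj$family,
                 fit_method = obj$fit_method, equations = equations,
                 required_characteristics = obj$required_characteristics,
                 n_stands = obj$n_stands),
            class = "ppm_models")
}
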