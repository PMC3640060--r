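# Per-stand parameter estimation.
#
# NRM (nonlinear regression method): least-squares match of the model CDF to
# the observed cumulative class frequencies, run by Levenberg-Marquardt in
# transformed coordinates (log p, log q, log(-r); logit a, log b, log c) so
# the optimizer trajectory cannot leave the feasible parameter domain -- the
# transform is what sidesteps the three-parameter Weibull's convergence
# pathology at the location parameter.
#
# MLEM (maximum likelihood): for the Weibull, the location is fixed at the
# lower limit of the minimum diameter class and (b, c) maximised on the
# shifted diameters; for the R distribution, full three-parameter likelihood
# maximisation (provided for completeness, the CDF route being primary).

dd_fit <- function(family, method, params, rss, r_squared, converged,
                   n_iterations, eval_points = NA_character_, loglik = NA_real_) {
  structure(list(family = family, method = method, params = params,
                 rss = rss, r_squared = r_squared, converged = converged,
                 n_iterations = n_iterations, eval_points = eval_points,
                 loglik = loglik),
            class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): %s\n  rss = %.4g, R2 = %.4f, converged = %s\n",
              x$family, x$method,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
              x$rss, x$r_squared, x$converged))
  invisible(x)
}

rss_to_r2 <- function(rss, Fobs) {
  tss <- sum((Fobs - mean(Fobs))^2)
  if (tss <= 0) return(NA_real_)
  1 - rss / tss
}

#' Initial parameter guesses from a histogram
#'
#' R distribution: location at the empirical median, scale from the
#' interquartile range of a logistic (IQR / (2 ln 3)), shape -1. Weibull:
#' location at the lower limit of the minimum diameter class, scale and shape
#' from the two-point percentile method at cumulative frequencies 0.333 and
#' 0.9. Guesses are always inside the feasible domain.
#'
#' @param hist a `dd_histogram`.
#' @param family `"rdist"` or `"weibull3"`.
#' @return named numeric vector of starting values.
#' @export
initial_guess <- function(hist, family = c("rdist", "weibull3")) {
  family <- match.arg(family)
  qs <- hist_quantile(hist, c(0.25, 0.333, 0.5, 0.75, 0.9))
  if (family == "rdist") {
    p0 <- max((qs[4] - qs[1]) / (2 * log(3)), 0.1)
    c(p = p0, q = max(qs[3], 0.5), r = -1)
  } else {
    occ <- hist$midpoint[hist$count > 0]
    a0 <- max(occ[1] - attr(hist, "width") / 2, 0)
    x1 <- qs[2]; x2 <- qs[5]
    if (x1 - a0 < 0.1) a0 <- max(x1 - attr(hist, "width"), 0)
    c0 <- (log(-log(0.1)) - log(-log(1 - 0.333))) / (log(x2 - a0) - log(x1 - a0))
    c0 <- min(max(c0, 0.3), 20)
    b0 <- (x1 - a0) / (-log(1 - 0.333))^(1 / c0)
    c(a = a0, b = max(b0, 0.1), c = c0)
  }
}

#' Fit a distribution to cumulative class frequencies (NRM)
#'
#' Minimises \eqn{\sum_k (F_k - F(x_k))^2} over the feasible parameter domain,
#' where \eqn{F_k} are the observed cumulative frequencies and \eqn{x_k} the
#' evaluation abscissae: class upper boundaries by default (where the
#' empirical cumulative frequency is exact), class midpoints as an option.
#'
#' @param hist a `dd_histogram` with at least 4 occupied classes.
#' @param family `"rdist"` or `"weibull3"`.
#' @param init optional named starting values (as [initial_guess()]).
#' @param eval_points `"upper"` (default) or `"midpoint"`.
#' @param max_iter iteration cap (default 500).
#' @param tol relative objective tolerance (default 1e-10).
#' @return a `dd_fit` with elements `params`, `rss`, `r_squared`, `converged`,
#'   `n_iterations`.
#' @export
fit_nrm <- function(hist, family = c("rdist", "weibull3"), init = NULL,
                    eval_points = c("upper", "midpoint"),
                    max_iter = 500, tol = 1e-10) {
  family <- match.arg(family)
  eval_points <- match.arg(eval_points)
  if (sum(hist$count > 0) < 4L)
    stop("NRM needs at least 4 occupied diameter classes for a 3-parameter family",
         call. = FALSE)
  xe <- if (eval_points == "upper") hist_upper(hist) else hist$midpoint
  Fobs <- hist$cumulative
  if (is.null(init)) init <- initial_guess(hist, family)

  if (family == "rdist") {
    theta0 <- c(log(init[["p"]]), log(init[["q"]]), log(-init[["r"]]))
    to_par <- function(th) c(p = exp(th[1]), q = exp(th[2]), r = -exp(th[3]))
    resid_fn <- function(th) {
      pr <- to_par(th)
      Fobs - prdist(xe, pr[["p"]], pr[["q"]], pr[["r"]])
    }
  } else {
    amax <- min(xe)   # location may not exceed the smallest evaluated diameter
    a0 <- min(max(init[["a"]] / amax, 0.02), 0.98)
    theta0 <- c(stats::qlogis(a0), log(init[["b"]]), log(init[["c"]]))
    to_par <- function(th) c(a = amax * stats::plogis(th[1]),
                             b = exp(th[2]), c = exp(th[3]))
    resid_fn <- function(th) {
      pr <- to_par(th)
      Fobs - pweibull3(xe, pr[["a"]], pr[["b"]], pr[["c"]])
    }
  }

  run_lm <- function(start) tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = min(max_iter, 1024), ftol = tol,
                         ptol = 1e-12)),
    error = function(e) NULL)

  fit <- run_lm(theta0)
  if (family == "rdist" && !is.null(fit)) {
    # The R distribution has a likelihood ridge: q -> 0 with r -> -Inf mimics
    # the same upper tail. If the search drifts onto it, profile the shape on
    # a grid, solving (p, q) at each fixed r, and restart from the best node.
    pr <- to_par(fit$par)
    if (pr[["r"]] < -30 || pr[["r"]] > -0.05 || pr[["q"]] < 0.3 * init[["q"]]) {
      prof <- lapply(-exp(seq(log(0.2), log(20), length.out = 25)), function(rfix) {
        res2 <- function(th2) Fobs - prdist(xe, exp(th2[1]), exp(th2[2]), rfix)
        f2 <- tryCatch(
          minpack.lm::nls.lm(par = theta0[1:2], fn = res2,
                             control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(f2)) NULL else list(rss = f2$deviance,
                                        theta = c(f2$par, log(-rfix)))
      })
      prof <- Filter(Negate(is.null), prof)
      if (length(prof)) {
        best <- prof[[which.min(vapply(prof, `[[`, 0, "rss"))]]
        refit <- run_lm(best$theta)
        fit <- if (!is.null(refit) && -exp(refit$par[3]) >= -30 &&
                   refit$deviance <= best$rss) refit
               else list(par = best$theta, deviance = best$rss,
                         info = 1L, niter = NA_integer_)
      }
    }
  }
  if (!is.null(fit)) {
    params <- to_par(fit$par)
    rss <- fit$deviance
    converged <- fit$info %in% 1:4
    niter <- fit$niter
  } else {
    # fall back on a derivative-free search over the same objective
    obj <- function(th) sum(resid_fn(th)^2)
    op <- stats::optim(theta0, obj, method = "Nelder-Mead",
                       control = list(maxit = max_iter * 4, reltol = tol))
    params <- to_par(op$par)
    rss <- op$value
    converged <- op$convergence == 0
    niter <- op$counts[["function"]]
  }
  dd_fit(family, "NRM", params, rss, rss_to_r2(rss, Fobs), converged,
         niter, eval_points)
}

#' Fit a three-parameter Weibull by maximum likelihood with fixed location
#'
#' The location is fixed at the lower limit of the minimum diameter class;
#' scale and shape maximise the Weibull likelihood of the shifted diameters.
#' If any diameter falls at or below the fixed location, the location is
#' shifted down to the class-system lower bound (and, as a last resort, just
#' below the smallest diameter) with a warning. RSS and R-squared are computed
#' afterwards on the cumulative class frequencies so the fit is comparable
#' with NRM.
#'
#' @param diameters vector of tree DBH, cm (at least 2 distinct values above
#'   the fixed location).
#' @param width,lower diameter-class convention (see [dbh_class()]).
#' @return a `dd_fit` with `method = "MLEM"` and the attained `loglik`.
#' @export
fit_mle_weibull3 <- function(diameters, width = 2, lower = 1) {
  hist <- diameter_histogram(diameters, width = width, lower = lower)
  occ <- hist$midpoint[hist$count > 0]
  a <- occ[1] - width / 2
  if (any(diameters <= a)) {
    warning("diameters at or below the fixed Weibull location; shifting the location down")
    a <- lower
    if (any(diameters <= a)) a <- min(diameters) - 1e-6
  }
  y <- diameters - a
  if (length(unique(y)) < 2L)
    stop("Weibull MLE needs at least 2 distinct diameters above the location",
         call. = FALSE)
  fd <- tryCatch(
    fitdistrplus::fitdist(y, "weibull", method = "mle"),
    error = function(e) NULL)
  if (!is.null(fd) && all(is.finite(fd$estimate))) {
    b <- unname(fd$estimate[["scale"]])
    cc <- unname(fd$estimate[["shape"]])
    ll <- fd$loglik
    converged <- TRUE
  } else {
    nll <- function(th) {
      v <- tryCatch(
        -sum(stats::dweibull(y, shape = exp(th[2]), scale = exp(th[1]), log = TRUE)),
        error = function(e) Inf)
      if (!is.finite(v)) 1e10 else v
    }
    start <- initial_guess(hist, "weibull3")
    op <- stats::optim(c(log(max(start[["b"]], 0.1)), log(start[["c"]])), nll,
                       method = "Nelder-Mead", control = list(maxit = 2000))
    b <- exp(op$par[1]); cc <- exp(op$par[2]); ll <- -op$value
    converged <- op$convergence == 0
  }
  Fobs <- hist$cumulative
  rss <- sum((Fobs - pweibull3(hist_upper(hist), a, b, cc))^2)
  dd_fit("weibull3", "MLEM", c(a = a, b = b, c = cc), rss,
         rss_to_r2(rss, Fobs), converged, NA_integer_, "upper", ll)
}

#' Fit the R distribution by maximum likelihood
#'
#' Maximises \eqn{\sum_i \log f(d_i)} over the feasible domain (log p, log q,
#' log(-r) coordinates), starting from quantile-based guesses, with a
#' Nelder-Mead search polished by BFGS. Non-convergence is flagged, never
#' raised. RSS and R-squared are computed on the cumulative class frequencies
#' for comparability with NRM.
#'
#' @param diameters vector of tree DBH, cm (at least 4 distinct values).
#' @param width,lower diameter-class convention used for the reported RSS.
#' @return a `dd_fit` with `method = "MLEM"` and the attained `loglik`.
#' @export
fit_mle_rdist <- function(diameters, width = 2, lower = 1) {
  if (length(unique(diameters)) < 4L)
    stop("R-distribution MLE needs at least 4 distinct diameters", call. = FALSE)
  qs <- stats::quantile(diameters, c(0.25, 0.5, 0.75), names = FALSE)
  p0 <- max((qs[3] - qs[1]) / (2 * log(3)), 0.05)
  theta0 <- c(log(p0), log(max(qs[2], 0.5)), 0)
  nll <- function(th) {
    v <- tryCatch(
      -sum(drdist(diameters, exp(th[1]), exp(th[2]), -exp(th[3]), log = TRUE)),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  op <- stats::optim(theta0, nll, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
  op2 <- tryCatch(stats::optim(op$par, nll, method = "BFGS",
                               control = list(maxit = 200)),
                  error = function(e) op)
  if (op2$value <= op$value) op <- op2
  params <- c(p = exp(op$par[1]), q = exp(op$par[2]), r = -exp(op$par[3]))
  converged <- op$convergence == 0 && op$value < 1e9
  hist <- tryCatch(diameter_histogram(diameters, width = width, lower = lower),
                   error = function(e) NULL)
  if (!is.null(hist)) {
    Fobs <- hist$cumulative
    rss <- sum((Fobs - prdist(hist_upper(hist), params[["p"]], params[["q"]],
                              params[["r"]]))^2)
    r2 <- rss_to_r2(rss, Fobs)
  } else {
    rss <- NA_real_; r2 <- NA_real_
  }
  dd_fit("rdist", "MLEM", params, rss, r2, converged,
         unname(op$counts["function"]), "upper", -op$value)
}

#' Fit every stand of a cohort
#'
#' Convenience wrapper running one fitting route over a list of stand records
#' and returning a per-stand table suitable for building prediction equations.
#'
#' @param stands list of `stand_record` objects.
#' @param family `"rdist"` or `"weibull3"`.
#' @param method `"nrm"` or `"mle"`.
#' @param width,lower diameter-class convention.
#' @param ... passed on to [fit_nrm()].
#' @return a data frame with one row per stand: `stand_id`, the parameters,
#'   `rss`, `r_squared`, `converged`, plus `family` and `method`.
#' @export
fit_stands <- function(stands, family = c("rdist", "weibull3"),
                       method = c("nrm", "mle"), width = 2, lower = 1, ...) {
  family <- match.arg(family)
  method <- match.arg(method)
  rows <- lapply(stands, function(s) {
    fit <- if (method == "nrm") {
      fit_nrm(diameter_histogram(s$diameters, width = width, lower = lower),
              family = family, ...)
    } else if (family == "weibull3") {
      fit_mle_weibull3(s$diameters, width = width, lower = lower)
    } else {
      fit_mle_rdist(s$diameters, width = width, lower = lower)
    }
    cbind(data.frame(stand_id = s$stand_id),
          as.data.frame(as.list(fit$params)),
          data.frame(rss = fit$rss, r_squared = fit$r_squared,
                     converged = fit$converged))
  })
  out <- do.call(rbind, rows)
  out$family <- family
  out$method <- if (method == "nrm") "NRM" else "MLEM"
  out
}
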