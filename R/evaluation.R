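# Goodness-of-fit evaluation: per-stand Kolmogorov-Smirnov decisions against
# a predicted CDF, residual sums of squares on the cumulative class
# frequencies, and cohort-level non-rejection rates stratified by thinning
# status. The KS decision uses the asymptotic critical value c(alpha)/sqrt(n)
# (c(0.05) = 1.358), valid because the tested distribution is predicted from
# stand characteristics, not refitted to the tested sample.

make_cdf <- function(family, params) {
  params <- unlist(params)
  if (family == "rdist") {
    p <- params[["p"]]; q <- params[["q"]]; r <- params[["r"]]
    function(x) prdist(x, p, q, r)
  } else if (family == "weibull3") {
    a <- params[["a"]]; b <- params[["b"]]; cc <- params[["c"]]
    function(x) pweibull3(x, a, b, cc)
  } else stop(sprintf("unknown family '%s'", family), call. = FALSE)
}

ks_critical <- function(n, alpha) sqrt(-log(alpha / 2) / 2) / sqrt(n)

#' Kolmogorov-Smirnov test of a sample against a fully specified CDF
#'
#' Computes \eqn{D = \sup_x |F_n(x) - F(x)|} from both one-sided suprema at
#' the sorted sample points and compares it with the asymptotic critical
#' value \eqn{c(\alpha)/\sqrt{n}} (1.358 at \eqn{\alpha = 0.05}).
#'
#' @param diameters sample of tree DBH, cm (at least 5 trees).
#' @param cdf a vectorised CDF function.
#' @param alpha significance level in (0, 1).
#' @return list with `statistic`, `critical`, `rejected`, `n`, `alpha`.
#' @export
ks_test_sample <- function(diameters, cdf, alpha = 0.05) {
  n <- length(diameters)
  if (n < 5L) stop("the KS test needs at least 5 trees", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  Fi <- cdf(sort(diameters))
  i <- seq_len(n)
  D <- max(i / n - Fi, Fi - (i - 1) / n)
  crit <- ks_critical(n, alpha)
  list(statistic = D, critical = crit, rejected = D > crit, n = n,
       alpha = alpha)
}

#' Kolmogorov-Smirnov test from binned cumulative frequencies
#'
#' Coarser fallback when only a histogram is available: the empirical step
#' function is known exactly at class boundaries, so the supremum is taken
#' over the class upper bounds (step top) and lower bounds (step bottom).
#'
#' @param hist a `dd_histogram`.
#' @inheritParams ks_test_sample
#' @return as [ks_test_sample()].
#' @export
ks_test_binned <- function(hist, cdf, alpha = 0.05) {
  n <- attr(hist, "n_total")
  if (n < 5L) stop("the KS test needs at least 5 trees", call. = FALSE)
  Fk <- hist$cumulative
  up <- cdf(hist_upper(hist))
  lo <- cdf(hist_lower(hist))
  Fprev <- c(0, Fk[-length(Fk)])
  D <- max(abs(Fk - up), abs(Fprev - lo))
  crit <- ks_critical(n, alpha)
  list(statistic = D, critical = crit, rejected = D > crit, n = n,
       alpha = alpha)
}

#' Residual sum of squares and coefficient of determination
#'
#' \eqn{RSS = \sum_k (obs_k - est_k)^2} and \eqn{R^2 = 1 - RSS / \sum_k
#' (obs_k - \overline{obs})^2} over the diameter classes of a stand.
#'
#' @param observed observed cumulative frequencies.
#' @param predicted model CDF values at the same abscissae.
#' @return list with `rss` and `r_squared`.
#' @export
rss_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 diameter classes", call. = FALSE)
  rss <- sum((observed - predicted)^2)
  list(rss = rss, r_squared = 1 - rss / sum((observed - mean(observed))^2))
}

#' Evaluate predicted distributions over a cohort
#'
#' For every stand, tests the predicted distribution against the raw tree
#' list (sample-based KS) and computes the RSS of the predicted CDF against
#' the observed cumulative class frequencies; aggregates the total RSS and
#' the KS non-rejection percentages overall and within the unthinned and
#' thinned strata.
#'
#' @param params data frame of predicted parameters
#'   (from [predict_stand_distribution()] or a fit table): `stand_id`,
#'   `family`, and `p`, `q`, `r` or `a`, `b`, `c`.
#' @param stands list of `stand_record` objects covering every `stand_id`.
#' @param alpha KS significance level.
#' @param width,lower diameter-class convention for the RSS.
#' @return a `dd_evaluation`: list with `per_stand` (data frame), `totals`
#'   (`total_rss`), and `non_rejection` percentages (`total`, `unthinned`,
#'   `thinned`).
#' @export
evaluate_cohort <- function(params, stands, alpha = 0.05, width = 2, lower = 1) {
  byid <- stats::setNames(stands, vapply(stands, `[[`, "", "stand_id"))
  missing <- setdiff(params$stand_id, names(byid))
  if (length(missing))
    stop(sprintf("no stand record for: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(params)), function(i) {
    s <- byid[[params$stand_id[i]]]
    fam <- params$family[i]
    par_cols <- if (fam == "rdist") c("p", "q", "r") else c("a", "b", "c")
    cdf <- make_cdf(fam, params[i, par_cols])
    ks <- ks_test_sample(s$diameters, cdf, alpha)
    hist <- diameter_histogram(s$diameters, width = width, lower = lower)
    gof <- rss_r2(hist$cumulative, cdf(hist_upper(hist)))
    data.frame(stand_id = s$stand_id, thinned = s$thinned, n = ks$n,
               ks_statistic = ks$statistic, ks_critical = ks$critical,
               rejected = ks$rejected, rss = gof$rss,
               r_squared = gof$r_squared)
  })
  per_stand <- do.call(rbind, rows)
  pct <- function(keep) {
    if (!any(keep)) return(NA_real_)
    100 * mean(!per_stand$rejected[keep])
  }
  structure(list(per_stand = per_stand,
                 totals = list(total_rss = sum(per_stand$rss)),
                 non_rejection = list(total = pct(rep(TRUE, nrow(per_stand))),
                                      unthinned = pct(!per_stand$thinned),
                                      thinned = pct(per_stand$thinned)),
                 alpha = alpha),
            class = "dd_evaluation")
}

#' @export
print.dd_evaluation <- function(x, ...) {
  nr <- x$non_rejection
  cat(sprintf("Cohort evaluation: %d stands, alpha = %g\n",
              nrow(x$per_stand), x$alpha))
  cat(sprintf("  total RSS          %.4f\n", x$totals$total_rss))
  cat(sprintf("  non-rejection      total %.2f%%  unthinned %s  thinned %s\n",
              nr$total,
              if (is.na(nr$unthinned)) "-" else sprintf("%.2f%%", nr$unthinned),
              if (is.na(nr$thinned)) "-" else sprintf("%.2f%%", nr$thinned)))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the per-stand table as delimited text and a structured summary
#' (method, related equations, number of characteristics, total RSS,
#' non-rejection rates) as key-value text.
#'
#' @param report a `dd_evaluation`.
#' @param per_stand_path,summary_path output paths.
#' @param models optional `ppm_models`, recorded in the summary.
#' @param delim field separator for the per-stand table.
#' @export
write_evaluation <- function(report, per_stand_path, summary_path,
                             models = NULL, delim = ",") {
  write_delim_table(report$per_stand, per_stand_path, delim)
  summary <- list(
    alpha = report$alpha,
    n_stands = nrow(report$per_stand),
    total_rss = signif(report$totals$total_rss, 6),
    non_rejection_pct = lapply(report$non_rejection, function(v)
      if (is.na(v)) NULL else signif(v, 6)))
  if (!is.null(models)) {
    summary$method <- models$method
    summary$family <- models$family
    summary$n_characteristics <- length(models$required_characteristics)
    summary$equations <- lapply(models$equations, function(eq)
      list(response = eq$response, r_squared = signif(eq$r_squared, 6)))
  }
  yaml::write_yaml(summary, summary_path)
  invisible(summary_path)
}
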