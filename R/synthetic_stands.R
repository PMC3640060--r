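# Synthetic plantation cohorts. The generator emulates the study design the
# modelling system assumes: five planting densities (1667, 3333, 5000, 6667,
# 10000 stems/ha) each measured at ages 6-10 yearly and 12-20 biennially in
# three replicate plots (150 fitting stands), plus an independent evaluation
# set of 63 unthinned and 96 thinned stands. Quadratic mean DBH follows a
# saturating age-density growth curve calibrated to the plantation ranges
# (about 5-18 cm over ages 6-20); stem density declines by self-thinning,
# faster at high planting density; and the per-stand distribution parameters
# are tied to stand characteristics by quadratic links with small noise --
# location q driven by Dg (the dominant signal), scale p by age, and the
# shape through log(-r) drifting with age so the inflection ordinate sits
# mostly in 0.4-0.6 and decreases with age. Diameters are drawn by inverse
# CDF, truncated below the class-system lower bound.

poly2 <- function(coefs, x) coefs[1] + coefs[2] * x + coefs[3] * x^2

clip_param <- function(x, lo, hi, what, cell) {
  if (x < lo || x > hi) {
    warning(sprintf("%s: generated %s = %.4g clipped to [%g, %g]",
                    cell, what, x, lo, hi))
    x <- min(max(x, lo), hi)
  }
  x
}

#' Describe a synthetic plantation cohort design
#'
#' Returns the full set of generator settings with the study-design defaults;
#' any field can be overridden by name. Ages follow the measurement schedule
#' (yearly to age 10, biennial after); the thinned stratum is generated at a
#' thinning age `lag` years before the measurement age, thinned from below by
#' `fraction`, and grown to the measurement age with stochastic individual
#' diameter increments.
#'
#' @param ... named overrides of the default fields.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(...) {
  design <- list(
    planting_densities = c(1667, 3333, 5000, 6667, 10000),
    fit_ages = c(6:10, seq(12, 20, 2)),
    replicates = 3,
    plot_area_fit = 0.06,     # ha
    plot_area_eval = 0.05,    # ha
    eval_unthinned = list(densities = c(1667, 3333, 5000),
                          ages = c(9, 10, seq(12, 20, 2)), replicates = 3),
    eval_thinned = list(densities = c(1667, 3333, 5000, 6667),
                        ages = seq(9, 23, 2), replicates = 3,
                        fraction = 0.2, lag = 4),
    generating_family = "rdist",
    # Dg (cm) = coef * age^age_exp * N0^dens_exp, lognormal noise
    growth = c(coef = 15.3, age_exp = 0.7, dens_exp = -0.258, sd_log = 0.04),
    # stems/ha = N0 * exp(-rate * (N0/10000)^dens_exp * (age - onset))
    mortality = c(rate = 0.039, dens_exp = 2.2, onset = 5),
    # R-distribution links: p quadratic in age, log(-r) linear in age;
    # the location q is implied by Dg (see draw_params)
    link_p = c(0.55, 0.05, 0.001),
    link_eta = c(-0.591, 0.0505, 0),
    # Weibull links (generating_family = "weibull3"): a linear in Dg,
    # c linear in age, b solved so the mean tracks Dg
    link_a = c(0, 0.45, 0),
    link_c = c(2.0, 0.06, 0),
    noise_sd = c(p = 0.05, eta = 0.08, c = 0.10, b = 0.04),
    site = c(mean = 14.5, sd = 1.0, min = 12, max = 18,
             h_rate = 0.105, ref_age = 20),
    bounds = list(p = c(0.3, 3), q = c(1.5, 30), r = c(-8, -0.2),
                  a_frac = 0.8, c = c(1.2, 9)),
    min_dbh = 1, class_width = 2, min_trees = 25)
  over <- list(...)
  bad <- setdiff(names(over), names(design))
  if (length(bad))
    stop(sprintf("unknown cohort_design field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  design[names(over)] <- over
  # normalise fields that may arrive as YAML lists
  vec_fields <- c("planting_densities", "fit_ages", "growth", "mortality",
                  "link_p", "link_eta", "link_a", "link_c",
                  "noise_sd", "site")
  design[vec_fields] <- lapply(design[vec_fields], unlist)
  design$bounds <- lapply(design$bounds, unlist)
  design$eval_unthinned <- lapply(design$eval_unthinned, unlist)
  design$eval_thinned <- lapply(design$eval_thinned, unlist)
  if (!design$generating_family %in% c("rdist", "weibull3"))
    stop("generating_family must be 'rdist' or 'weibull3'", call. = FALSE)
  if (any(design$planting_densities <= 0) || any(design$fit_ages <= 0))
    stop("densities and ages must be positive", call. = FALSE)
  fr <- design$eval_thinned$fraction
  if (fr <= 0 || fr >= 1)
    stop("thinning fraction must lie in (0, 1)", call. = FALSE)
  class(design) <- "cohort_design"
  design
}

dg_target <- function(age, density, design) {
  g <- design$growth
  g[["coef"]] * age^g[["age_exp"]] * density^g[["dens_exp"]]
}

density_at <- function(age, density, design) {
  m <- design$mortality
  rate <- m[["rate"]] * (density / 10000)^m[["dens_exp"]]
  density * exp(-rate * max(age - m[["onset"]], 0))
}

# The stand's location-type parameter is not noised independently: it is
# solved so that the distribution's quadratic mean equals the stand's Dg,
# exactly as in a measured plot, where Dg is computed from the same trees the
# distribution describes. For the R distribution the standardised variable
# T = (x - q)/p has the generalized-logistic moments E[T] = psi(nu) + gamma
# and Var[T] = psi'(nu) + pi^2/6 with nu = -r, so E[x^2] = Dg^2 is a
# quadratic in q with a closed-form positive root.
draw_params <- function(age, dg, design, cell) {
  ns <- design$noise_sd
  b <- design$bounds
  if (design$generating_family == "rdist") {
    p <- clip_param(poly2(design$link_p, age) + stats::rnorm(1, 0, ns[["p"]]),
                    b$p[1], b$p[2], "p", cell)
    eta <- poly2(design$link_eta, age) + stats::rnorm(1, 0, ns[["eta"]])
    r <- clip_param(-exp(eta), b$r[1], b$r[2], "r", cell)
    nu <- -r
    muT <- digamma(nu) + 0.57721566490153286
    ST <- trigamma(nu) + pi^2 / 6 + muT^2
    disc <- (p * muT)^2 - p^2 * ST + dg^2
    q <- if (disc > 0) -p * muT + sqrt(disc) else dg - p * muT
    q <- clip_param(q, b$q[1], b$q[2], "q", cell)
    list(family = "rdist", p = p, q = q, r = r)
  } else {
    a <- max(poly2(design$link_a, dg), 0)
    a <- min(a, b$a_frac * dg)
    cc <- clip_param(poly2(design$link_c, age) + stats::rnorm(1, 0, ns[["c"]]),
                     b$c[1], b$c[2], "c", cell)
    g1 <- gamma(1 + 1 / cc); g2 <- gamma(1 + 2 / cc)
    disc <- a^2 * g1^2 - g2 * (a^2 - dg^2)
    bb <- if (disc > 0) (-a * g1 + sqrt(disc)) / g2 else (dg - a) / g1
    bb <- bb * exp(stats::rnorm(1, 0, ns[["b"]]))
    list(family = "weibull3", a = a, b = bb, c = cc)
  }
}

draw_diameters <- function(n, params, design, cell) {
  lo <- design$min_dbh
  if (params$family == "rdist") {
    umin <- prdist(lo, params$p, params$q, params$r)
    if (umin > 0.25)
      stop(sprintf("%s: %.0f%% of the generated distribution lies below the %g cm bound",
                   cell, 100 * umin, lo), call. = FALSE)
    qrdist(stats::runif(n, umin, 1 - 1e-12), params$p, params$q, params$r)
  } else {
    umin <- pweibull3(lo, params$a, params$b, params$c)
    if (umin > 0.25)
      stop(sprintf("%s: %.0f%% of the generated distribution lies below the %g cm bound",
                   cell, 100 * umin, lo), call. = FALSE)
    qweibull3(pmax(stats::runif(n, umin, 1 - 1e-12), 1e-12),
              params$a, params$b, params$c)
  }
}

site_and_heights <- function(age, design) {
  s <- design$site
  si <- min(max(stats::rnorm(1, s[["mean"]], s[["sd"]])), s[["max"]])
  si <- max(si, s[["min"]])
  shape <- (1 - exp(-s[["h_rate"]] * age)) / (1 - exp(-s[["h_rate"]] * s[["ref_age"]]))
  hd <- si * shape * exp(stats::rnorm(1, 0, 0.03))
  hm <- max(0.9 * hd - 0.3 + stats::rnorm(1, 0, 0.15), 1.3)
  list(site_index = si, dominant_height = hd, mean_height = hm)
}

#' Generate one synthetic stand
#'
#' Draws stand characteristics and a tree list for one design cell,
#' reproducibly for a given seed. For a thinned stand the tree list is first
#' generated at the thinning age (`age - lag`), the smallest `fraction` of
#' trees is removed (thinning from below), and survivors receive stochastic
#' diameter increments matching the expected quadratic-mean growth to the
#' measurement age.
#'
#' @param age measurement age, years.
#' @param planting_density stems/ha.
#' @param design a `cohort_design`.
#' @param seed integer seed (each stand is a pure function of its seed).
#' @param thinned logical; generate a thinned stand?
#' @param stand_id identifier.
#' @param plot_area plot area, ha (defaults to the design's fitting-plot area).
#' @return a `stand_record` carrying the generating parameters in attribute
#'   `"gen_params"` (and, for thinned stands, the pre-thinning tree list in
#'   `"pre_thinning"`).
#' @export
generate_stand <- function(age, planting_density, design = cohort_design(),
                           seed = 1L, thinned = FALSE, stand_id = NULL,
                           plot_area = design$plot_area_fit) {
  set.seed(seed)
  cell <- sprintf("cell(age=%g, density=%g%s)", age, planting_density,
                  if (thinned) ", thinned" else "")
  if (is.null(stand_id)) stand_id <- sprintf("S%d", seed)
  gen_age <- if (thinned) max(age - design$eval_thinned$lag,
                              design$mortality[["onset"]]) else age
  N <- density_at(gen_age, planting_density, design)
  dg <- dg_target(gen_age, planting_density, design) *
    exp(stats::rnorm(1, 0, design$growth[["sd_log"]]))
  params <- draw_params(gen_age, dg, design, cell)
  n <- max(design$min_trees, round(plot_area * N))
  d <- draw_diameters(n, params, design, cell)
  pre <- NULL
  if (thinned) {
    # Thin from below at the thinning age, then let the residual stand grow
    # and re-equilibrate to the measurement age: removal raises the quadratic
    # mean (a selection boost carried through the growth curve), and the
    # surviving collective redevelops the distribution shape implied by the
    # parameter links at its final characteristics -- the premise under which
    # thinned stands can be evaluated with equations trained on unthinned
    # ones. The redraw is truncated just above the pre-thinning minimum, so
    # the thinned list always starts above it.
    pre <- d
    keep <- ceiling(length(d) * (1 - design$eval_thinned$fraction))
    surv <- sort(d, decreasing = TRUE)[seq_len(keep)]
    boost <- quadratic_mean_dbh(surv) / quadratic_mean_dbh(d)
    dg_fin <- dg_target(age, planting_density, design) * boost *
      exp(stats::rnorm(1, 0, design$growth[["sd_log"]]))
    params <- draw_params(age, dg_fin, design, cell)
    b_lo <- min(d) + 0.1
    u_lo <- if (params$family == "rdist")
      prdist(b_lo, params$p, params$q, params$r)
    else pweibull3(b_lo, params$a, params$b, params$c)
    u <- stats::runif(keep, max(u_lo, 1e-12), 1 - 1e-12)
    d <- if (params$family == "rdist") qrdist(u, params$p, params$q, params$r)
         else qweibull3(u, params$a, params$b, params$c)
    N <- N * (1 - design$eval_thinned$fraction)
  }
  hs <- site_and_heights(age, design)
  out <- stand_record(stand_id, d, age,
                      planting_density = planting_density,
                      stand_density = round(N),
                      site_index = hs$site_index,
                      mean_height = hs$mean_height,
                      dominant_height = hs$dominant_height,
                      thinned = thinned)
  attr(out, "gen_params") <- params
  if (!is.null(pre)) attr(out, "pre_thinning") <- pre
  out
}

#' Generate disjoint fitting and evaluation cohorts
#'
#' Builds the default study layout: 150 fitting stands (5 densities x 10
#' measurement ages x 3 replicates) and 159 evaluation stands (63 unthinned +
#' 96 thinned). The whole cohort is a pure function of `(design, seed)`.
#'
#' @param design a `cohort_design`.
#' @param seed integer seed.
#' @return list with elements `fitting` and `evaluation`, each a list of
#'   `stand_record` objects.
#' @export
generate_cohorts <- function(design = cohort_design(), seed = 1L) {
  fit_grid <- expand.grid(density = design$planting_densities,
                          age = design$fit_ages,
                          rep = seq_len(design$replicates))
  eu <- design$eval_unthinned
  et <- design$eval_thinned
  eu_grid <- expand.grid(density = eu$densities, age = eu$ages,
                         rep = seq_len(eu$replicates))
  et_grid <- expand.grid(density = et$densities, age = et$ages,
                         rep = seq_len(et$replicates))
  total <- nrow(fit_grid) + nrow(eu_grid) + nrow(et_grid)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  gen <- function(grid, offset, prefix, thinned, area) {
    lapply(seq_len(nrow(grid)), function(i)
      generate_stand(grid$age[i], grid$density[i], design,
                     seed = seeds[offset + i], thinned = thinned,
                     stand_id = sprintf("%s%03d", prefix, i),
                     plot_area = area))
  }
  fitting <- gen(fit_grid, 0L, "F", FALSE, design$plot_area_fit)
  ev_un <- gen(eu_grid, nrow(fit_grid), "EU", FALSE, design$plot_area_eval)
  ev_th <- gen(et_grid, nrow(fit_grid) + nrow(eu_grid), "ET", TRUE,
               design$plot_area_eval)
  list(fitting = fitting, evaluation = c(ev_un, ev_th))
}

#' Read / write a cohort design as structured text
#'
#' @param path file path.
#' @param design a `cohort_design`.
#' @return `read_cohort_design` returns a `cohort_design`.
#' @export
read_cohort_design <- function(path) {
  do.call(cohort_design, yaml::read_yaml(path))
}

#' @rdname read_cohort_design
#' @export
write_cohort_design <- function(design, path) {
  # named atomic vectors must become maps, or their names are lost
  to_obj <- function(x) {
    if (is.list(x)) lapply(x, to_obj)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_obj(unclass(design)), path, precision = 15)
  invisible(path)
}
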