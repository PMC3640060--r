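# A stand record couples one plot's tree list (DBH, cm) with the stand
# characteristics the prediction equations draw on.

#' Create a stand record
#'
#' @param stand_id identifier (character or coercible).
#' @param diameters vector of tree DBH, cm (all positive).
#' @param age stand age, years.
#' @param planting_density initial density, stems/ha.
#' @param stand_density current density, stems/ha.
#' @param site_index site index (dominant height at reference age 20), m.
#' @param mean_height stand mean height, m.
#' @param dominant_height stand dominant height, m.
#' @param thinned logical; has the stand been thinned?
#' @return a `stand_record` object.
#' @export
stand_record <- function(stand_id, diameters, age,
                         planting_density = NA_real_, stand_density = NA_real_,
                         site_index = NA_real_, mean_height = NA_real_,
                         dominant_height = NA_real_, thinned = FALSE) {
  if (length(diameters) < 1L || any(!is.finite(diameters)) || any(diameters <= 0))
    stop("a stand record needs at least one positive, finite diameter", call. = FALSE)
  if (!is.na(age) && (!is.finite(age) || age <= 0))
    stop("stand age must be positive", call. = FALSE)
  if (!isTRUE(thinned) && is.finite(stand_density) && is.finite(planting_density) &&
      stand_density > planting_density + 1e-8)
    warning(sprintf("stand %s: current density exceeds planting density in an unthinned stand",
                    stand_id))
  structure(list(stand_id = as.character(stand_id),
                 diameters = as.numeric(diameters),
                 age = age,
                 planting_density = planting_density,
                 stand_density = stand_density,
                 site_index = site_index,
                 mean_height = mean_height,
                 dominant_height = dominant_height,
                 thinned = isTRUE(thinned)),
            class = "stand_record")
}

#' @export
print.stand_record <- function(x, ...) {
  cat(sprintf("Stand %s: %d trees, age %g yr, Dg %.2f cm%s\n",
              x$stand_id, length(x$diameters), x$age,
              quadratic_mean_dbh(x$diameters),
              if (x$thinned) " (thinned)" else ""))
  invisible(x)
}

#' Tabulate stand characteristics for a list of stand records
#'
#' Returns one row per stand with the characteristics used by the prediction
#' equations, including the quadratic mean DBH `dg` computed from the tree
#' list.
#'
#' @param stands a list of `stand_record` objects.
#' @return a data frame.
#' @export
as_stand_table <- function(stands) {
  if (inherits(stands, "stand_record")) stands <- list(stands)
  do.call(rbind, lapply(stands, function(s) {
    data.frame(stand_id = s$stand_id,
               age = s$age,
               planting_density = s$planting_density,
               stand_density = s$stand_density,
               site_index = s$site_index,
               mean_height = s$mean_height,
               dominant_height = s$dominant_height,
               dg = quadratic_mean_dbh(s$diameters),
               n_trees = length(s$diameters),
               thinned = s$thinned)
  }))
}
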