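# Delimited-text readers and writers for tree lists, stand-characteristic
# tables, histograms and fit tables. Comma is the default separator; tab is
# accepted. Numeric output is fixed to 6 significant digits so re-running a
# stage with the same seed reproduces byte-identical tables.

read_delim_checked <- function(path, required, delim = ",", what = "table") {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  df
}

format_numeric <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

write_delim_table <- function(df, path, delim = ",") {
  utils::write.table(format_numeric(df), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tree list
#'
#' Expects columns `stand_id` and `dbh_cm`, one row per tree.
#'
#' @param path file path.
#' @param delim field separator (`","` default, `"\t"` accepted).
#' @return a data frame.
#' @export
read_tree_list <- function(path, delim = ",") {
  df <- read_delim_checked(path, c("stand_id", "dbh_cm"), delim, "tree list")
  bad <- which(!is.finite(df$dbh_cm) | df$dbh_cm <= 0)
  if (length(bad))
    stop(sprintf("tree list %s: non-positive or missing dbh_cm at data row %d",
                 path, bad[1]), call. = FALSE)
  df
}

#' Read a stand-characteristics table
#'
#' Expects columns `stand_id`, `age_yr`, `planting_density`, `stand_density`,
#' `site_index_m`, `mean_height_m`, `dominant_height_m`, `thinned`.
#'
#' @inheritParams read_tree_list
#' @return a data frame with package-internal column names (`age`,
#'   `site_index`, ...).
#' @export
read_stand_table <- function(path, delim = ",") {
  req <- c("stand_id", "age_yr", "planting_density", "stand_density",
           "site_index_m", "mean_height_m", "dominant_height_m", "thinned")
  df <- read_delim_checked(path, req, delim, "stand table")
  out <- data.frame(stand_id = as.character(df$stand_id),
                    age = df$age_yr,
                    planting_density = df$planting_density,
                    stand_density = df$stand_density,
                    site_index = df$site_index_m,
                    mean_height = df$mean_height_m,
                    dominant_height = df$dominant_height_m,
                    thinned = as.logical(df$thinned))
  if ("dg_cm" %in% names(df)) out$dg <- df$dg_cm
  out
}

#' Read a stand-characteristics table leniently
#'
#' Like [read_stand_table()] but requires only `stand_id`: whichever
#' characteristic columns are present (`age_yr`, `planting_density`,
#' `stand_density`, `site_index_m`, `mean_height_m`, `dominant_height_m`,
#' `dg_cm`, `thinned`) are mapped to package-internal names. Prediction
#' methods validate for themselves that the characteristics they need are
#' present, so a table holding only `stand_id` and `dg_cm` is enough for a
#' quadratic-mean-DBH-only method.
#'
#' @inheritParams read_tree_list
#' @return a data frame.
#' @export
read_characteristics <- function(path, delim = ",") {
  df <- read_delim_checked(path, "stand_id", delim, "characteristics table")
  map <- c(age_yr = "age", planting_density = "planting_density",
           stand_density = "stand_density", site_index_m = "site_index",
           mean_height_m = "mean_height", dominant_height_m = "dominant_height",
           dg_cm = "dg", thinned = "thinned")
  out <- data.frame(stand_id = as.character(df$stand_id))
  for (src in names(map))
    if (src %in% names(df)) out[[map[[src]]]] <- df[[src]]
  if ("thinned" %in% names(out)) out$thinned <- as.logical(out$thinned)
  out
}

#' Combine a tree list and a stand table into stand records
#'
#' @param trees data frame from [read_tree_list()].
#' @param stands data frame from [read_stand_table()]; may be `NULL`, in which
#'   case only ages of `NA` are available and stand-level prediction is not.
#' @return a list of `stand_record` objects.
#' @export
make_stand_records <- function(trees, stands = NULL) {
  ids <- unique(trees$stand_id)
  lapply(ids, function(id) {
    d <- trees$dbh_cm[trees$stand_id == id]
    if (is.null(stands)) {
      stand_record(id, d, age = NA_real_)
    } else {
      row <- stands[stands$stand_id == id, , drop = FALSE]
      if (nrow(row) != 1L)
        stop(sprintf("stand table has %d rows for stand %s (need exactly 1)",
                     nrow(row), id), call. = FALSE)
      stand_record(id, d, age = row$age,
                   planting_density = row$planting_density,
                   stand_density = row$stand_density,
                   site_index = row$site_index,
                   mean_height = row$mean_height,
                   dominant_height = row$dominant_height,
                   thinned = row$thinned)
    }
  })
}

#' Write a cohort of stand records to delimited text
#'
#' Writes the tree list (`stand_id`, `dbh_cm`) and the characteristics table
#' in the formats the readers expect.
#'
#' @param stands list of `stand_record` objects.
#' @param trees_path,stands_path output file paths.
#' @param delim field separator.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(stands, trees_path, stands_path, delim = ",") {
  trees <- do.call(rbind, lapply(stands, function(s)
    data.frame(stand_id = s$stand_id, dbh_cm = s$diameters)))
  tab <- as_stand_table(stands)
  out <- data.frame(stand_id = tab$stand_id, age_yr = tab$age,
                    planting_density = tab$planting_density,
                    stand_density = tab$stand_density,
                    site_index_m = tab$site_index,
                    mean_height_m = tab$mean_height,
                    dominant_height_m = tab$dominant_height,
                    dg_cm = tab$dg,
                    thinned = tab$thinned)
  write_delim_table(trees, trees_path, delim)
  write_delim_table(out, stands_path, delim)
  invisible(c(trees_path, stands_path))
}

#' Write a diameter-class histogram
#'
#' @param hist a `dd_histogram`.
#' @param path output file path.
#' @param delim field separator.
#' @export
write_histogram <- function(hist, path, delim = ",") {
  df <- data.frame(class_midpoint = hist$midpoint, count = hist$count,
                   frequency = hist$frequency, cumulative = hist$cumulative)
  write_delim_table(df, path, delim)
}
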