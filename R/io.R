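# CSV contracts for the four input streams and the pipeline outputs.
# All dates are ISO-8601; a missing value is an empty cell.

#' Read the input CSV streams
#'
#' Thin schema-checked readers for the four input tables: speciated
#' monitor records (`site_id`, `date`, `pm10`, `pm25`, one column per
#' species), monitor sites (`site_id`, `latitude`, `longitude`), ZIP
#' units (`zip_id`, `latitude`, `longitude`, `radius_km`), ED visits
#' (`visit_id`, `admission_date`, `zip_id`, `dx1`...`dxK`), and ZIP-day
#' meteorology (`zip_id`, `date`, `tmax`, `dewpoint`, optionally `pm25`,
#' `no2`, `o3`).
#'
#' @param path File path.
#' @return A tibble with parsed dates.
#' @name readers
NULL

read_checked <- function(path, required, date_cols = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(basename(path), " lacks required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  for (dc in date_cols) df[[dc]] <- as_iso_date(df[[dc]], dc)
  df
}

#' @rdname readers
#' @export
read_monitor_csv <- function(path) {
  read_checked(path, c("site_id", "date", "pm10", "pm25"), "date")
}

#' @rdname readers
#' @export
read_sites_csv <- function(path) {
  read_checked(path, c("site_id", "latitude", "longitude"))
}

#' @rdname readers
#' @export
read_zips_csv <- function(path) {
  read_checked(path, c("zip_id", "latitude", "longitude", "radius_km"))
}

#' @rdname readers
#' @export
read_visits_csv <- function(path) {
  df <- read_checked(path, c("visit_id", "admission_date", "zip_id"),
                     "admission_date")
  if (!length(grep("^dx", names(df)))) {
    abort(paste0(basename(path), " has no diagnosis columns (dx1, dx2, ...)."))
  }
  df$zip_id <- as.character(df$zip_id)
  df
}

#' @rdname readers
#' @export
read_met_csv <- function(path) {
  df <- read_checked(path, c("zip_id", "date", "tmax", "dewpoint"), "date")
  df$zip_id <- as.character(df$zip_id)
  df
}

write_output_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(df, path, na = "")
  path
}
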