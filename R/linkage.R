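# Buffer-based exposure linkage: ZIP units (modelled as discs with a
# centroid and effective radius) are assigned to the nearest monitoring
# site whose buffer they touch, and lagged dust labels are served per ZIP.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. Vectorised over
#' coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Decimal-degree coordinates.
#' @return Distance(s) in km.
#' @export
#' @examples
#' geodesic_km(0, 0, 0, 1) # one degree of arc on the equator
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) all(abs(lat) <= 90, na.rm = TRUE) &&
    all(abs(lon) <= 180, na.rm = TRUE)
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    abort("Coordinates out of range: need |lat| <= 90, |lon| <= 180.")
  }
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371) # r in km -> result in km
}

#' Minimum distance from a ZIP disc to a site
#'
#' Distance from the nearest part of the ZIP's effective disc to the
#' site: `max(0, centroid_distance - radius_km)`. A site inside the disc
#' is at distance zero. This operationalises "wholly or partially within
#' a buffer" as minimum boundary distance at or below the buffer.
#'
#' @param zip_lat,zip_lon ZIP centroid coordinates.
#' @param radius_km Effective ZIP radius (>= 0).
#' @param site_lat,site_lon Site coordinates.
#' @return Distance(s) in km.
#' @export
zip_site_distance_km <- function(zip_lat, zip_lon, radius_km,
                                 site_lat, site_lon) {
  if (any(radius_km < 0)) abort("`radius_km` must be >= 0.")
  pmax(0, geodesic_km(zip_lat, zip_lon, site_lat, site_lon) - radius_km)
}

#' Assign ZIP units to monitoring sites under a distance buffer
#'
#' A ZIP is linked iff its minimum disc distance to at least one site is
#' at or below `buffer_km` (inclusive). Among qualifying sites the one
#' with the smallest centroid distance wins; exact centroid-distance ties
#' break lexicographically on `site_id`. Unlinked ZIPs are absent from
#' the result.
#'
#' @param zip_units Tibble: zip_id, latitude, longitude, radius_km.
#' @param sites Tibble: site_id, latitude, longitude.
#' @param buffer_km Buffer radius, km (> 0). 50 for the primary analysis,
#'   15 for the proximity sensitivity analysis.
#' @return Tibble: zip_id, site_id, centroid_km, min_distance_km, with
#'   attribute `buffer_km`.
#' @export
assign_sites <- function(zip_units, sites, buffer_km = 50) {
  if (buffer_km <= 0) abort("`buffer_km` must be > 0.")
  pairs <- tidyr::expand_grid(
    zip_idx = seq_len(nrow(zip_units)),
    site_idx = seq_len(nrow(sites))
  )
  pairs$zip_id <- zip_units$zip_id[pairs$zip_idx]
  pairs$site_id <- sites$site_id[pairs$site_idx]
  pairs$centroid_km <- geodesic_km(
    zip_units$latitude[pairs$zip_idx], zip_units$longitude[pairs$zip_idx],
    sites$latitude[pairs$site_idx], sites$longitude[pairs$site_idx]
  )
  pairs$min_distance_km <- pmax(
    0, pairs$centroid_km - zip_units$radius_km[pairs$zip_idx]
  )
  linked <- pairs |>
    dplyr::filter(.data$min_distance_km <= buffer_km) |>
    dplyr::arrange(.data$zip_id, .data$centroid_km, .data$site_id) |>
    dplyr::distinct(.data$zip_id, .keep_all = TRUE) |>
    dplyr::select("zip_id", "site_id", "centroid_km", "min_distance_km")
  attr(linked, "buffer_km") <- buffer_km
  linked
}

#' Look up the lagged dust indicator for a ZIP
#'
#' Returns the dust label of the ZIP's linked site on `date - lag`.
#' Vectorised over `zip_id`/`date`. An unsampled or unlabelled site-day
#' yields `NA`; an unlinked ZIP is an error.
#'
#' @param labels Label table (site_id, date, dust), e.g. from
#'   [classify_series()].
#' @param linkage Output of [assign_sites()].
#' @param zip_id,date ZIP(s) and visit date(s).
#' @param lag Integer lag in 0..5.
#' @return Integer vector in {0, 1, NA}.
#' @export
lookup_exposure <- function(labels, linkage, zip_id, date, lag = 0L) {
  if (!all(lag %in% 0:5)) abort("`lag` must lie in 0..5.")
  date <- as_iso_date(date, "date")
  site <- linkage$site_id[match(zip_id, linkage$zip_id)]
  if (anyNA(site)) {
    abort(paste0("ZIP(s) not linked to any site: ",
                 paste(unique(zip_id[is.na(site)]), collapse = ", "), "."))
  }
  lab <- setNames(labels$dust, paste(labels$site_id, labels$date))
  unname(lab[paste(site, date - lag)])
}
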