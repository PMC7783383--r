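# Great-circle arithmetic and distance-travelled summaries.

EARTH_RADIUS_KM <- 6371.0

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop_input("coordinates must be finite")
  }
  if (any(lat < -90 | lat > 90)) stop_input("latitude out of range [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop_input("longitude out of range [-180, 180]")
  invisible(NULL)
}

#' Haversine great-circle distance
#'
#' Distance in kilometres between points on a sphere of radius 6371 km.
#' All arguments are in decimal degrees and recycle to a common length.
#'
#' @param lat1,lon1 coordinates of the first point(s).
#' @param lat2,lon2 coordinates of the second point(s).
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(51.5074, -0.1278, 52.2053, 0.1218) # London -> Cambridge
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Full pairwise distance matrix between two coordinate sets (km).
haversine_matrix <- function(lat1, lon1, lat2, lon2) {
  n1 <- length(lat1)
  n2 <- length(lat2)
  outer_lat1 <- matrix(lat1, n1, n2)
  outer_lon1 <- matrix(lon1, n1, n2)
  outer_lat2 <- matrix(lat2, n1, n2, byrow = TRUE)
  outer_lon2 <- matrix(lon2, n1, n2, byrow = TRUE)
  matrix(haversine_km(outer_lat1, outer_lon1, outer_lat2, outer_lon2), n1, n2)
}

#' Population-weighted centroid
#'
#' Weighted mean of latitude and longitude in plain degree space. This planar
#' approximation is appropriate at the scale of small census geographies far
#' from the antimeridian; it is how population-weighted LSOA centroids are
#' treated throughout the package.
#'
#' @param lat,lon coordinates in decimal degrees.
#' @param weights non-negative weights (e.g. resident populations); at least
#'   one must be positive.
#' @return A list with elements `lat` and `lon`.
#' @export
population_weighted_centroid <- function(lat, lon, weights) {
  check_coords(lat, lon)
  if (length(lat) != length(weights) || length(lon) != length(weights)) {
    stop_input("coordinates and weights must have equal length")
  }
  if (any(weights < 0)) stop_input("weights must be non-negative")
  total <- sum(weights)
  if (total <= 0) stop_input("weights must not all be zero")
  list(lat = sum(lat * weights) / total, lon = sum(lon * weights) / total)
}

#' Per-procedure distance-travelled summary
#'
#' Computes the straight-line (haversine) distance from each event's LSOA
#' population-weighted centroid to its (merged) treatment site, and summarises
#' the mean distance per procedure code and overall.
#'
#' @param events data frame of procedure events with columns `opcs3`,
#'   `lsoa_code`, `site_code` (merged codes).
#' @param lsoas data frame with columns `lsoa_code`, `lat`, `lon`.
#' @param registry a [merge_nearby_sites()] registry (its `$sites` table
#'   provides merged-site coordinates), or a data frame with columns
#'   `site_code`, `lat`, `lon`.
#' @return A list: `per_procedure` (tibble `opcs3`, `n_events`, `mean_km`),
#'   `overall_mean_km`, and `n_skipped` (events whose LSOA or site could not
#'   be resolved, dropped with a warning).
#' @export
distance_travelled_summary <- function(events, lsoas, registry) {
  sites <- if (is.data.frame(registry)) registry else registry$sites
  d <- event_distances(events, lsoas, sites)
  skipped <- sum(is.na(d))
  if (skipped > 0) {
    warning(skipped, " events skipped: unresolvable LSOA or site", call. = FALSE)
  }
  keep <- !is.na(d)
  ev <- events[keep, , drop = FALSE]
  dk <- d[keep]
  per <- tibble::tibble(opcs3 = ev$opcs3, km = dk) |>
    dplyr::group_by(.data$opcs3) |>
    dplyr::summarise(n_events = dplyr::n(), mean_km = mean(.data$km)) |>
    dplyr::arrange(dplyr::desc(.data$n_events), .data$opcs3)
  list(per_procedure = per,
       overall_mean_km = if (length(dk)) mean(dk) else NA_real_,
       n_skipped = skipped)
}

# Haversine distance per event row; NA where LSOA or site is unknown.
event_distances <- function(events, lsoas, sites) {
  il <- match(events$lsoa_code, lsoas$lsoa_code)
  is <- match(events$site_code, sites$site_code)
  ok <- !is.na(il) & !is.na(is)
  out <- rep(NA_real_, nrow(events))
  if (any(ok)) {
    out[ok] <- haversine_km(lsoas$lat[il[ok]], lsoas$lon[il[ok]],
                            sites$lat[is[ok]], sites$lon[is[ok]])
  }
  out
}
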