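#' Great-circle distance to the urban center
#'
#' Haversine distance on a sphere of radius 6371.0088 km. The default center
#' is downtown Toronto, the reference point of the Greater-Toronto-Area
#' urbanization gradient this pipeline targets.
#'
#' @param lat,lon decimal degrees (WGS84); vectors recycle against each other
#' @param center `c(lat, lon)` of the city center
#' @return distance in km
#' @export
distance_to_center <- function(lat, lon, center = c(43.6563, -79.3809)) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180) ||
      abs(center[1]) > 90 || abs(center[2]) > 180)
    stop("coordinates out of range")
  ## geosphere wants (lon, lat) and metres
  geosphere::distHaversine(cbind(lon, lat), c(center[2], center[1]),
                           r = 6371008.8) / 1000
}

#' Classify sampling sites as urban or rural
#'
#' Two schemes, applied per sampling site: by distance (`urban` iff the
#' site's distance to the city center is <= 30 km, boundary inclusive) and,
#' when an `urban_score` column is present, by score (`urban` iff score > 0,
#' boundary exclusive; the score is an externally computed landcover metric
#' consumed as data). All samples at one site share its labels; if samples
#' at a site carry coordinates more than 1 km apart a warning is emitted and
#' the site centroid is used.
#'
#' @param frame metadata data.frame (`sample_id`, `site_id`, `lat`, `lon`,
#'   optional `urban_score`)
#' @param center,dist_threshold_km classification parameters
#' @return `frame` with columns `dist_km`, `habitat_by_distance` and (when
#'   scores exist) `habitat_by_score`
#' @export
classify_habitat <- function(frame, center = c(43.6563, -79.3809),
                             dist_threshold_km = 30) {
  stopifnot(all(c("site_id", "lat", "lon") %in% names(frame)))
  cent <- stats::aggregate(cbind(lat, lon) ~ site_id, data = frame, FUN = mean)
  ## detect conflicting within-site coordinates
  for (s in cent$site_id) {
    rows <- frame[frame$site_id == s, ]
    if (nrow(rows) > 1) {
      d <- distance_to_center(rows$lat, rows$lon,
                              center = c(cent$lat[cent$site_id == s],
                                         cent$lon[cent$site_id == s]))
      if (any(d > 1))
        warning("site ", s, " has samples > 1 km apart; using centroid")
    }
  }
  cent$dist_km <- distance_to_center(cent$lat, cent$lon, center = center)
  cent$habitat_by_distance <-
    ifelse(cent$dist_km <= dist_threshold_km, "urban", "rural")
  m <- match(frame$site_id, cent$site_id)
  frame$dist_km <- cent$dist_km[m]
  frame$habitat_by_distance <- cent$habitat_by_distance[m]
  if ("urban_score" %in% names(frame)) {
    sc <- stats::aggregate(urban_score ~ site_id, data = frame, FUN = mean)
    frame$habitat_by_score <-
      ifelse(sc$urban_score[match(frame$site_id, sc$site_id)] > 0,
             "urban", "rural")
  }
  frame
}
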