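# Great-circle geometry shared by every module. All distances in the package
# are haversine distances on a sphere of mean radius 6371.0088 km.

.EARTH_RADIUS_M <- 6371008.8

#' Haversine great-circle distance in kilometres
#'
#' Distance between points given as longitude/latitude in decimal degrees
#' (WGS84), computed on a sphere of mean radius 6371.0088 km. Inputs recycle
#' as in [geosphere::distHaversine()].
#'
#' @param p1,p2 Two-column matrices (or length-2 vectors) of
#'   longitude, latitude in decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @export
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_M) / 1000
}

# Full pairwise distance matrix in km for an n x 2 lon/lat matrix.
pairwise_km <- function(pts) {
  geosphere::distm(pts, fun = geosphere::distHaversine) / 1000 *
    (.EARTH_RADIUS_M / 6378137)
}
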