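# Transformation between WGS84 geographic coordinates and the Dutch national
# planar grid RD New (EPSG:28992), using the published polynomial
# approximation of Schreutelkamp & Strang van Hees. Accuracy is better than
# ~0.5 m inside the Netherlands, far below the 25 m grid cells used here.

.rd_x0 <- 155000
.rd_y0 <- 463000
.rd_phi0 <- 52.15517440
.rd_lam0 <- 5.38720621

# columns: p (power of first argument), q (power of second), coefficient
.rd2wgs_phi <- matrix(c(
  0, 1, 3235.65389,
  2, 0, -32.58297,
  0, 2, -0.24750,
  2, 1, -0.84978,
  0, 3, -0.06550,
  2, 2, -0.01709,
  1, 0, -0.00738,
  4, 0, 0.00530,
  2, 3, -0.00039,
  4, 1, 0.00033,
  1, 1, -0.00012), ncol = 3, byrow = TRUE)

.rd2wgs_lam <- matrix(c(
  1, 0, 5260.52916,
  1, 1, 105.94684,
  1, 2, 2.45656,
  3, 0, -0.81885,
  1, 3, 0.05594,
  3, 1, -0.05607,
  0, 1, 0.01199,
  3, 2, -0.00256,
  1, 4, 0.00128,
  0, 2, 0.00022,
  2, 0, -0.00022,
  5, 0, 0.00026), ncol = 3, byrow = TRUE)

.wgs2rd_x <- matrix(c(
  0, 1, 190094.945,
  1, 1, -11832.228,
  2, 1, -114.221,
  0, 3, -32.391,
  1, 0, -0.705,
  3, 1, -2.340,
  1, 3, -0.608,
  0, 2, -0.008,
  2, 3, 0.148), ncol = 3, byrow = TRUE)

.wgs2rd_y <- matrix(c(
  1, 0, 309056.544,
  0, 2, 3638.893,
  2, 0, 73.077,
  1, 2, -157.984,
  3, 0, 59.788,
  0, 1, 0.433,
  2, 2, -6.439,
  1, 1, -0.032,
  0, 4, 0.092,
  1, 4, -0.054), ncol = 3, byrow = TRUE)

.poly_eval <- function(coefs, u, v) {
  out <- 0
  for (k in seq_len(nrow(coefs))) {
    out <- out + coefs[k, 3] * u^coefs[k, 1] * v^coefs[k, 2]
  }
  out
}

#' Convert RD New (EPSG:28992) coordinates to WGS84
#'
#' @param x,y numeric vectors of RD New easting/northing in metres.
#' @return A data frame with columns `lon` and `lat` in decimal degrees.
#' @seealso [wgs84_to_rd()]
#' @export
rd_to_wgs84 <- function(x, y) {
  dx <- (x - .rd_x0) * 1e-5
  dy <- (y - .rd_y0) * 1e-5
  lat <- .rd_phi0 + .poly_eval(.rd2wgs_phi, dx, dy) / 3600
  lon <- .rd_lam0 + .poly_eval(.rd2wgs_lam, dx, dy) / 3600
  data.frame(lon = lon, lat = lat)
}

#' Convert WGS84 coordinates to RD New (EPSG:28992)
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @return A data frame with columns `x` and `y` in metres (RD New).
#' @export
wgs84_to_rd <- function(lon, lat) {
  dphi <- 0.36 * (lat - .rd_phi0)
  dlam <- 0.36 * (lon - .rd_lam0)
  x <- .rd_x0 + .poly_eval(.wgs2rd_x, dphi, dlam)
  y <- .rd_y0 + .poly_eval(.wgs2rd_y, dphi, dlam)
  data.frame(x = x, y = y)
}

# Resolve a projection specification into a list with fwd(lon, lat)->x,y and
# inv(x, y)->lon,lat. "EPSG:28992" is built in; a list with fwd/inv function
# elements is accepted for any other metric CRS.
.resolve_projection <- function(projection) {
  if (is.character(projection) && length(projection) == 1) {
    if (toupper(projection) != "EPSG:28992") {
      stop("only EPSG:28992 is built in; supply list(fwd =, inv =) for other projections")
    }
    return(list(
      fwd = function(lon, lat) wgs84_to_rd(lon, lat),
      inv = function(x, y) rd_to_wgs84(x, y)
    ))
  }
  if (is.list(projection) && is.function(projection$fwd) && is.function(projection$inv)) {
    return(projection)
  }
  stop("projection must be \"EPSG:28992\" or a list(fwd =, inv =) of functions")
}
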