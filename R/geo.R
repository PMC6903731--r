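# Spherical geometry, the working projection, and planar polygon utilities.
# All distances are on a sphere of radius 6371.0 km; all planar work happens
# in a south-polar Lambert azimuthal equal-area plane with km units.

#' Sphere radius used throughout the package (km)
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0

#' Central meridian of the working projection (degrees east)
#' @keywords internal
PROJ_LON0 <- -60

#' Normalize longitudes to (-180, 180]
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector with each value wrapped into `(-180, 180]`.
#' @examples
#' normalize_lon(c(181, -540, 180, -180))
#' @export
normalize_lon <- function(lon) {
  r <- ((lon + 180) %% 360) - 180
  r[!is.na(r) & r == -180] <- 180
  r
}

#' Project lon/lat to the working equal-area plane
#'
#' South-polar Lambert azimuthal equal-area projection centered on the pole
#' with central meridian 60 degrees W, spherical earth of radius 6371 km.
#' The projection is exactly area-preserving, so polygon areas computed in
#' this plane (km^2) are true spherical areas; it has no dateline seam,
#' which matters for tracks spanning 170W--25W.
#'
#' @param lon,lat coordinates in degrees (WGS84 treated as spherical).
#' @return a two-column matrix with columns `x`, `y` in km.
#' @seealso [unproject_laea()]
#' @export
project_laea <- function(lon, lat) {
  lam <- (lon - PROJ_LON0) * pi / 180
  colat2 <- (90 + lat) * pi / 360          # half colatitude from south pole
  rho <- 2 * EARTH_RADIUS_KM * sin(colat2)
  cbind(x = rho * sin(lam), y = rho * cos(lam))
}

#' Inverse of the working projection
#'
#' @param x,y planar coordinates in km (see [project_laea()]).
#' @return a two-column matrix with columns `lon`, `lat` in degrees,
#'   longitudes in `(-180, 180]`.
#' @export
unproject_laea <- function(x, y) {
  rho <- sqrt(x^2 + y^2)
  s <- pmin(1, rho / (2 * EARTH_RADIUS_KM))
  lat <- 2 * asin(s) * 180 / pi - 90
  lon <- ifelse(rho > 0, PROJ_LON0 + atan2(x, y) * 180 / pi, PROJ_LON0)
  cbind(lon = normalize_lon(lon), lat = lat)
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km, the package-wide
#' distance convention.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectors recycle.
#' @return distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

# ---- planar polygon utilities -------------------------------------------

#' Signed area of a planar polygon (shoelace formula)
#'
#' Positive for counter-clockwise rings. The closing edge is implicit.
#'
#' @param x,y ring vertex coordinates.
#' @return signed area in the square of the coordinate unit.
#' @export
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting test of points against a single ring. Points exactly on an
#' edge may land on either side; callers needing a deterministic boundary
#' convention should not rely on this for boundary points.
#'
#' @param px,py point coordinates (vectors).
#' @param vx,vy ring vertex coordinates.
#' @return logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Clip a polygon against a convex polygon (Sutherland--Hodgman)
#'
#' The subject ring may be arbitrary (convex or not, any orientation); the
#' clip ring must be convex. Orientation of the subject is preserved, so
#' signed areas of clipped holes stay negative.
#'
#' @param sx,sy subject ring vertices.
#' @param cx,cy convex clip ring vertices (any orientation).
#' @return list with `x`, `y` of the clipped ring (possibly length 0).
#' @export
clip_polygon_convex <- function(sx, sy, cx, cy) {
  # ensure clip ring is counter-clockwise so "inside" is left of each edge
  if (polygon_area(cx, cy) < 0) { cx <- rev(cx); cy <- rev(cy) }
  nx <- sx; ny <- sy
  nc <- length(cx)
  for (e in seq_len(nc)) {
    if (length(nx) == 0) break
    ax <- cx[e]; ay <- cy[e]
    bx <- cx[if (e == nc) 1 else e + 1]; by <- cy[if (e == nc) 1 else e + 1]
    # signed side of each subject vertex relative to clip edge a->b
    side <- (bx - ax) * (ny - ay) - (by - ay) * (nx - ax)
    keep_in <- side >= 0
    ox <- numeric(0); oy <- numeric(0)
    m <- length(nx)
    for (i in seq_len(m)) {
      jprev <- if (i == 1) m else i - 1
      if (keep_in[i] != keep_in[jprev]) {
        # intersection of subject edge with clip edge line
        t <- side[jprev] / (side[jprev] - side[i])
        ox <- c(ox, nx[jprev] + t * (nx[i] - nx[jprev]))
        oy <- c(oy, ny[jprev] + t * (ny[i] - ny[jprev]))
      }
      if (keep_in[i]) { ox <- c(ox, nx[i]); oy <- c(oy, ny[i]) }
    }
    nx <- ox; ny <- oy
  }
  list(x = nx, y = ny)
}

# insert vertices so no edge exceeds max_len (same units as coords);
# used before reprojecting rings so long straight edges follow the surface
densify_ring <- function(x, y, max_len) {
  n <- length(x)
  if (n < 2) return(list(x = x, y = y))
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
    k <- max(1L, ceiling(d / max_len))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    ox <- c(ox, x[i] + t * (x[j] - x[i]))
    oy <- c(oy, y[i] + t * (y[j] - y[i]))
  }
  list(x = ox, y = oy)
}
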