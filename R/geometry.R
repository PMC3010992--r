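# Great-circle geometry: reference routes and signed cross-track deviations.
# Spherical Earth, radius EARTH_RADIUS_KM; all distances in km.

.norm_lon <- function(lon) ((lon + 180) %% 360) - 180

.check_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2 || anyNA(p) || !all(is.finite(p)))
    stop(what, " must be a finite (lon, lat) pair")
  if (p[2] < -90 || p[2] > 90)
    stop(what, ": latitude must lie in [-90, 90]")
  c(.norm_lon(p[1]), p[2])
}

.as_lonlat <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("lon", "lat")])
  if (is.matrix(p)) {
    if (ncol(p) != 2) stop("coordinate matrix must have two columns")
    p[, 1] <- .norm_lon(p[, 1])
    return(p)
  }
  matrix(.check_point(p), ncol = 2)
}

#' Great-circle distance between two points
#'
#' Shortest distance on the sphere between two (lon, lat) points, in km,
#' using radius [EARTH_RADIUS_KM].
#'
#' @param p1,p2 Numeric `c(lon, lat)` in degrees, or two-column matrices
#'   (lon, lat) of equal length for vectorized use.
#' @return Distance(s) in km.
#' @examples
#' gc_distance(c(0, 0), c(1, 0))  # one degree of longitude at the equator
#' @export
gc_distance <- function(p1, p2) {
  p1 <- .as_lonlat(p1)
  p2 <- .as_lonlat(p2)
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
}

#' Construct a great-circle reference route
#'
#' The assumed intended migration route: the shortest path on the sphere
#' from `start` to `end`.
#'
#' @param start,end `c(lon, lat)` in degrees; must differ.
#' @return An object of class `"gc_route"`: list with `start`, `end` and
#'   `length_km`.
#' @export
gc_route <- function(start, end) {
  start <- .check_point(start, "start")
  end <- .check_point(end, "end")
  len <- gc_distance(start, end)
  if (len < 1e-9) stop("degenerate route: start and end coincide")
  structure(list(start = start, end = end, length_km = len),
            class = "gc_route")
}

#' @export
print.gc_route <- function(x, ...) {
  cat(sprintf("Great-circle route (%.3f, %.3f) -> (%.3f, %.3f), %.1f km\n",
              x$start[1], x$start[2], x$end[1], x$end[2], x$length_km))
  invisible(x)
}

#' Signed cross-track deviation from a great-circle route
#'
#' Perpendicular great-circle distance from a point to the (full) great
#' circle through the route's endpoints. The sign encodes the side:
#' positive to the LEFT of the start-to-end direction of travel, negative to
#' the right. A point on the route returns 0. The distance is to the full
#' great circle, not clamped to the start-end arc, because the route is a
#' line of reference for deviations, which are locally perpendicular;
#' `clamp = TRUE` instead returns the (signed) distance to the nearest point
#' of the arc itself.
#'
#' @param p `c(lon, lat)` or a two-column (lon, lat) matrix.
#' @param route A [gc_route()].
#' @param clamp If `TRUE`, restrict the nearest point to the start-end arc.
#' @return Signed deviation(s) in km.
#' @export
cross_track_deviation <- function(p, route, clamp = FALSE) {
  if (!inherits(route, "gc_route")) stop("route must be a gc_route")
  p <- .as_lonlat(p)
  # geosphere's sign convention is negative left of the path; flip it
  d <- -as.numeric(geosphere::dist2gc(route$start, route$end, p,
                                      r = EARTH_RADIUS_KM, sign = TRUE))
  quarter <- pi * EARTH_RADIUS_KM / 2
  if (any(abs(abs(d) - quarter) < 1e-6, na.rm = TRUE))
    stop("point lies at a pole of the route's great circle; ",
         "cross-track deviation is undefined")
  if (clamp) {
    R <- EARTH_RADIUS_KM
    n <- nrow(p)
    ds <- gc_distance(p, matrix(route$start, n, 2, byrow = TRUE))
    de <- gc_distance(p, matrix(route$end, n, 2, byrow = TRUE))
    # spherical right triangle: distance from each endpoint to the foot
    clamp01 <- function(z) pmin(1, pmax(-1, z))
    as_ <- R * acos(clamp01(cos(ds / R) / cos(d / R)))
    ae_ <- R * acos(clamp01(cos(de / R) / cos(d / R)))
    outside <- (as_ + ae_) > route$length_km + 0.1
    if (any(outside))
      d[outside] <- sign(d[outside]) * pmin(ds[outside], de[outside])
  }
  d
}

#' Cross-track deviation series of a regularized track
#'
#' Computes one signed deviation per daily location of a regularized track,
#' relative to a great-circle route. By default the route is defined by the
#' track's first and last non-missing locations, so the first and last
#' deviations are (numerically) zero. Missing days yield `NA` deviations and
#' are retained, keeping the series on the daily grid the state-space model
#' expects.
#'
#' @param track A regularized track `data.frame` (columns `day_index`,
#'   `lon`, `lat`, optionally `animal_id`, `sex`, `date`), as produced by
#'   [regularize()], or a two-column (lon, lat) matrix. A multi-animal frame
#'   is split by `animal_id`, with one route per animal.
#' @param route Optional [gc_route()] overriding the default endpoints.
#' @return A `data.frame` with columns `animal_id` (if available), `sex`
#'   (if available), `day_index`, `date` (if available) and `deviation_km`,
#'   with the route(s) attached as attribute `"route"`.
#' @export
deviation_series <- function(track, route = NULL) {
  if (is.matrix(track)) {
    track <- data.frame(day_index = seq_len(nrow(track)),
                        lon = track[, 1], lat = track[, 2])
  }
  if (!is.null(track$animal_id) && length(unique(track$animal_id)) > 1) {
    parts <- lapply(split(track, track$animal_id), deviation_series,
                    route = route)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "route") <- lapply(parts, attr, "route")
    return(out)
  }
  if (nrow(track) == 0) stop("empty track")
  obs <- is.finite(track$lon) & is.finite(track$lat)
  if (!any(obs)) stop("track has no non-missing locations")
  if (is.null(route)) {
    i1 <- which(obs)[1]
    i2 <- which(obs)[sum(obs)]
    if (i1 == i2) stop("track needs at least two non-missing locations")
    route <- gc_route(c(track$lon[i1], track$lat[i1]),
                      c(track$lon[i2], track$lat[i2]))
  }
  dev <- rep(NA_real_, nrow(track))
  dev[obs] <- cross_track_deviation(
    cbind(track$lon[obs], track$lat[obs]), route)
  out <- data.frame(day_index = track$day_index, deviation_km = dev)
  if (!is.null(track$animal_id)) out <- cbind(
    data.frame(animal_id = track$animal_id), out)
  if (!is.null(track$sex)) out$sex <- track$sex
  if (!is.null(track$date)) out$date <- track$date
  attr(out, "route") <- route
  out
}

#' Write a deviation series to delimited text
#'
#' @param dev A `data.frame` from [deviation_series()].
#' @param file Output path (CSV).
#' @export
write_deviations <- function(dev, file) {
  utils::write.csv(dev, file, row.names = FALSE)
  invisible(file)
}

# --- internal spherical helpers used by the track generator ----------------

.to_xyz <- function(p) {
  lam <- p[, 1] * pi / 180
  phi <- p[, 2] * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.from_xyz <- function(v) {
  v <- v / sqrt(rowSums(v^2))
  cbind(.norm_lon(atan2(v[, 2], v[, 1]) * 180 / pi),
        asin(pmin(1, pmax(-1, v[, 3]))) * 180 / pi)
}

# interpolate along the great circle through start/end; frac may lie outside
# [0, 1] (the full circle), via spherical linear interpolation
.gc_interp <- function(start, end, frac) {
  a <- .to_xyz(matrix(start, 1))[1, ]
  b <- .to_xyz(matrix(end, 1))[1, ]
  om <- acos(pmin(1, pmax(-1, sum(a * b))))
  s <- sin(om)
  w1 <- sin((1 - frac) * om) / s
  w2 <- sin(frac * om) / s
  .from_xyz(cbind(w1 * a[1] + w2 * b[1],
                  w1 * a[2] + w2 * b[2],
                  w1 * a[3] + w2 * b[3]))
}

# destination moving d_km from p at initial bearing brg (degrees), sphere
.gc_dest <- function(p, brg, d_km) {
  out <- geosphere::destPoint(p, brg, d_km * 1000,
                              a = EARTH_RADIUS_KM * 1000, f = 0)
  cbind(.norm_lon(out[, 1]), out[, 2])
}

# offset points perpendicular to the local direction of travel toward
# route_end; positive d_km = left of travel
.offset_left <- function(pts, route_end, d_km) {
  brg <- as.numeric(geosphere::bearing(pts, matrix(route_end, nrow(pts), 2,
                                                   byrow = TRUE)))
  res <- pts
  pos <- which(d_km > 1e-12)
  neg <- which(d_km < -1e-12)
  if (length(pos))
    res[pos, ] <- .gc_dest(pts[pos, , drop = FALSE],
                           (brg[pos] - 90) %% 360, d_km[pos])
  if (length(neg))
    res[neg, ] <- .gc_dest(pts[neg, , drop = FALSE],
                           (brg[neg] + 90) %% 360, -d_km[neg])
  res
}
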