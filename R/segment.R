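# Delimiting the migratory portion of a track: departure from the
# travel-rate peak, cessation from a persistent reversal of longitude
# change, plus current-boundary splitting and edge trimming.

#' Robust nonlinear smoother (running median + Hanning pass)
#'
#' A running median of the given (odd) window, followed by a single Hanning
#' pass (weights 1/4, 1/2, 1/4); the endpoints are copied from the median
#' stage. Single-point spikes are removed entirely by the median stage.
#'
#' @param series Numeric vector, no missing values.
#' @param window_days Odd window width, at least 3; default 7.
#' @return Smoothed vector of the same length.
#' @export
robust_smooth <- function(series, window_days = 7) {
  if (window_days < 3 || window_days %% 2 == 0)
    stop("window_days must be odd and >= 3")
  n <- length(series)
  if (n < window_days) stop("series shorter than the smoother window")
  if (anyNA(series)) stop("series must not contain missing values")
  med <- stats::runmed(series, k = window_days, endrule = "keep")
  out <- med
  if (n >= 3)
    out[2:(n - 1)] <- 0.25 * med[1:(n - 2)] + 0.5 * med[2:(n - 1)] +
      0.25 * med[3:n]
  as.numeric(out)
}

# fill interior NAs by linear interpolation, extend ends by nearest value
.na_fill <- function(x) {
  if (!anyNA(x)) return(x)
  ix <- which(is.finite(x))
  if (length(ix) < 2) stop("series has fewer than two finite values")
  stats::approx(ix, x[ix], xout = seq_along(x), rule = 2)$y
}

#' Detect the start of migration from travel rates
#'
#' Departure from the residence area shows as a peak in travel rate. The
#' rate series is robust-smoothed and the index of its global maximum is
#' returned, ignoring the first `exclude_days` entries (early elevated
#' speeds are typically post-tagging behaviour, not departure).
#'
#' @param rates Travel-rate series in km/day (see [travel_rates()]); `NA`s
#'   are interpolated before smoothing.
#' @param exclude_days Number of leading entries to ignore; default 7.
#' @param window_days Smoother window; default 7.
#' @return Index into `rates` of the smoothed peak (if `rates` has names,
#'   the named day index is returned as attribute `"day"`).
#' @export
detect_migration_start <- function(rates, exclude_days = 7,
                                   window_days = 7) {
  n <- length(rates)
  if (n <= exclude_days + window_days)
    stop("rate series too short for start detection")
  sm <- robust_smooth(.na_fill(as.numeric(rates)), window_days)
  i0 <- exclude_days + 1L
  idx <- i0 + which.max(sm[i0:n]) - 1L
  if (!is.null(names(rates)))
    attr(idx, "day") <- as.integer(names(rates)[idx])
  idx
}

#' Detect the end of migration from longitude changes
#'
#' Post-migration behaviour (foraging, breeding-site selection) shows as
#' frequent changes in direction. The longitude series is robust-smoothed
#' and differenced; the end is the first index after `start` where the sign
#' of the change reverses relative to the migratory direction and the
#' reversed sign persists for at least `persist_days` consecutive days. If
#' no such reversal exists the last index is returned with a warning.
#'
#' @param longitudes Daily longitude series (degrees); `NA`s interpolated.
#' @param start Day index at which migration starts.
#' @param persist_days Minimum persistence of the reversed direction;
#'   default 5.
#' @param window_days Smoother window; default 7.
#' @return Day index of migration end.
#' @export
detect_migration_end <- function(longitudes, start, persist_days = 5,
                                 window_days = 7) {
  n <- length(longitudes)
  if (start >= n - persist_days)
    stop("start too close to the end of the series")
  sm <- robust_smooth(.na_fill(as.numeric(longitudes)), window_days)
  d <- diff(sm)
  ref <- d[start:min(n - 1, start + 13)]
  s0 <- sign(sum(sign(ref[ref != 0])))
  if (s0 == 0) s0 <- sign(sm[min(n, start + 14)] - sm[start])
  if (s0 == 0) s0 <- 1
  for (i in seq(start + 1, n - persist_days)) {
    seg <- d[i:(i + persist_days - 1)]
    if (all(seg * s0 < 0)) return(i)
  }
  warning("no persistent direction reversal found; using last index")
  n
}

#' Split a regularized track at a current-boundary polyline
#'
#' For testing whether animals re-plan their route after being displaced by
#' a strong current (e.g. the Gulf Stream), a track is split at the boundary
#' crossing: `after` starts at the first location south of the boundary
#' that is never followed by a return to north of boundary + band. A fresh
#' great-circle route should then be defined from `after`'s first location
#' (this is what [deviation_series()] does by default).
#'
#' @param rtrack Regularized track `data.frame` (one animal).
#' @param boundary `data.frame` or matrix with columns (lon, lat): the mean
#'   position of the current, vertices ordered west to east. The boundary
#'   latitude at a track longitude is obtained by linear interpolation.
#' @param band_km Half-width of the boundary band in km; default 0.
#' @return List with elements `before` and `after` (row subsets of
#'   `rtrack`) and `crossing_index` (the `day_index` at which `after`
#'   starts).
#' @export
split_at_boundary <- function(rtrack, boundary, band_km = 0) {
  b <- as.matrix(as.data.frame(boundary)[, 1:2])
  if (nrow(b) < 2) stop("boundary polyline needs at least 2 vertices")
  obs <- is.finite(rtrack$lon) & is.finite(rtrack$lat)
  blat <- rep(NA_real_, nrow(rtrack))
  blat[obs] <- stats::approx(b[, 1], b[, 2], xout = rtrack$lon[obs],
                             rule = 2)$y
  deg_per_km <- 180 / (pi * EARTH_RADIUS_KM)
  south <- rtrack$lat < blat
  north_of_band <- rtrack$lat > blat + band_km * deg_per_km
  idx <- NA_integer_
  for (i in which(obs & south)) {
    later <- which(obs)[which(obs) >= i]
    if (!any(north_of_band[later], na.rm = TRUE)) {
      idx <- i
      break
    }
  }
  if (is.na(idx)) {
    id <- if (is.null(rtrack$animal_id)) "track" else rtrack$animal_id[1]
    stop("track ", id, " does not cross the boundary southward")
  }
  if (idx == 1) {
    id <- if (is.null(rtrack$animal_id)) "track" else rtrack$animal_id[1]
    stop("track ", id, " lies entirely south of the boundary")
  }
  list(before = rtrack[seq_len(idx - 1), , drop = FALSE],
       after = rtrack[idx:nrow(rtrack), , drop = FALSE],
       crossing_index = rtrack$day_index[idx])
}

#' Trim the edges of a deviation series
#'
#' Drops `floor(frac * T)` values from each end of a series. Deviations are
#' near zero at the route endpoints by construction (the route is tied down
#' there), so the model can be checked for sensitivity to this tie-down by
#' re-fitting after removing the first and last 2.5% of each series.
#'
#' @param series Numeric vector, or a `data.frame` (trimmed row-wise, per
#'   animal if an `animal_id` column is present).
#' @param frac Fraction to drop at each end, in `[0, 0.5)`; default 0.025.
#' @return Trimmed object of the same type.
#' @export
trim_edges <- function(series, frac = 0.025) {
  if (frac < 0 || frac >= 0.5) stop("frac must lie in [0, 0.5)")
  if (is.data.frame(series)) {
    if (!is.null(series$animal_id) &&
        length(unique(series$animal_id)) > 1) {
      out <- do.call(rbind, lapply(split(series, series$animal_id),
                                   trim_edges, frac = frac))
      rownames(out) <- NULL
      return(out)
    }
    k <- floor(frac * nrow(series))
    if (k == 0) return(series)
    return(series[(k + 1):(nrow(series) - k), , drop = FALSE])
  }
  n <- length(series)
  k <- floor(frac * n)
  if (k == 0) return(series)
  series[(k + 1):(n - k)]
}

#' Delimit the migratory portion of a regularized track
#'
#' Convenience wrapper: computes travel rates, detects the migration start
#' (travel-rate peak) and end (longitude change point), and returns the
#' migratory row subset. Manual bounds override the detectors, mirroring
#' the practice of confirming automatic change points against the mapped
#' track.
#'
#' @param rtrack Regularized track `data.frame` (one animal).
#' @param exclude_days,persist_days,window_days Detector settings.
#' @param manual Optional `c(start_day, end_day)` override.
#' @return List with `bounds` (`c(start, end)` day indices), `method`
#'   (`"auto"` or `"manual"`) and `track` (the migratory rows).
#' @export
segment_migration <- function(rtrack, exclude_days = 7, persist_days = 5,
                              window_days = 7, manual = NULL) {
  if (!is.null(manual)) {
    s <- manual[1]
    e <- manual[2]
    if (!(s >= 1 && s < e && e <= max(rtrack$day_index)))
      stop("invalid manual bounds")
    method <- "manual"
  } else {
    r <- travel_rates(rtrack)
    i <- detect_migration_start(r, exclude_days, window_days)
    s <- as.integer(names(r)[i])
    lon_daily <- .na_fill(rtrack$lon)
    e <- detect_migration_end(lon_daily, start = s, persist_days,
                              window_days)
    method <- "auto"
  }
  sel <- rtrack$day_index >= s & rtrack$day_index <= e
  list(bounds = c(start = s, end = e), method = method,
       track = rtrack[sel, , drop = FALSE])
}
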