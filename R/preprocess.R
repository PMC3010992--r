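# Regularization of raw multi-fix-per-day tracks to one robust location per
# 24 h window.

#' Read raw track fixes from delimited text
#'
#' Expects one row per satellite fix. Column names are configurable;
#' timestamps are parsed as ISO-8601 in UTC. The Argos location-class code,
#' if present, is carried along but never used in estimation (reported
#' per-class standard errors are not relied upon).
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @param columns Named list mapping the internal names `id`, `sex`, `time`,
#'   `lon`, `lat`, `lc` to column names in the file. `sex` and `lc` are
#'   optional.
#' @return A `data.frame` with columns `animal_id`, `sex`, `timestamp`
#'   (POSIXct, UTC), `lon`, `lat`, `loc_class`, sorted by animal and time.
#' @export
read_track_fixes <- function(file, sep = ",",
                             columns = list(id = "animal_id", sex = "sex",
                                            time = "timestamp", lon = "lon",
                                            lat = "lat", lc = "loc_class")) {
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("id", "time", "lon", "lat")
  for (k in need)
    if (!columns[[k]] %in% names(raw))
      stop("missing column: ", columns[[k]])
  out <- data.frame(
    animal_id = as.character(raw[[columns$id]]),
    sex = if (!is.null(columns$sex) && columns$sex %in% names(raw))
      as.character(raw[[columns$sex]]) else "unknown",
    timestamp = as.POSIXct(raw[[columns$time]], tz = "UTC"),
    lon = as.numeric(raw[[columns$lon]]),
    lat = as.numeric(raw[[columns$lat]]),
    loc_class = if (!is.null(columns$lc) && columns$lc %in% names(raw))
      as.character(raw[[columns$lc]]) else NA_character_,
    stringsAsFactors = FALSE)
  if (anyNA(out$timestamp)) stop("unparseable timestamps in ", file)
  out[order(out$animal_id, out$timestamp), , drop = FALSE]
}

#' Partition a track's fixes into equal time windows
#'
#' Fixes are assigned to half-open windows `[t0 + k*step, t0 + (k+1)*step)`.
#' Empty windows between the first and last fix are retained as
#' placeholders.
#'
#' @param track `data.frame` with a POSIXct `timestamp` column (one animal).
#' @param step_hours Window length in hours (> 0), default 24.
#' @param anchor Window origin `t0`; defaults to the first fix's timestamp.
#' @return List with `index` (1-based window index per fix), `n_windows`,
#'   and `window_start` (POSIXct of window 1's left edge).
#' @export
partition_windows <- function(track, step_hours = 24, anchor = NULL) {
  if (step_hours <= 0) stop("step_hours must be positive")
  tt <- track$timestamp
  if (is.null(tt)) stop("track must have a timestamp column")
  t0 <- if (is.null(anchor)) min(tt) else as.POSIXct(anchor, tz = "UTC")
  hrs <- as.numeric(difftime(tt, t0, units = "hours"))
  idx <- floor(hrs / step_hours) + 1L
  list(index = as.integer(idx), n_windows = max(idx),
       window_start = t0)
}

# mean and covariance determinant of a point subset
.subset_det <- function(pts, ix) {
  s <- pts[ix, , drop = FALSE]
  det(stats::cov(s))
}

#' Minimum Covariance Determinant location estimate
#'
#' Returns the mean of the size-`h` subset of 2-D points whose sample
#' covariance matrix has the smallest determinant; robust to up to `n - h`
#' gross outliers. For `n <= 12` the search over subsets is exhaustive;
#' beyond that a concentration (C-step) search from many random starts is
#' used. Coordinates are used as given (daily windows are local enough that
#' degree anisotropy is negligible at this scale).
#'
#' @param points Two-column matrix or data.frame of (lon, lat).
#' @param h Subset size; default `floor((n + 3) / 2)`, the maximal-breakdown
#'   choice in two dimensions.
#' @return `c(lon, lat)` of the estimate, with the selected subset indices
#'   as attribute `"subset"`.
#' @export
mcd_location <- function(points, h = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two columns")
  n <- nrow(pts)
  if (n < 4)
    stop("MCD needs at least 4 points; use median_location() instead")
  if (is.null(h)) h <- floor((n + 3) / 2)
  h <- as.integer(h)
  if (h < 3 || h > n) stop("h must lie in [3, n]")

  if (n <= 12) {
    subs <- utils::combn(n, h)
    dets <- apply(subs, 2, function(ix) .subset_det(pts, ix))
    best <- subs[, which.min(dets)]
  } else {
    best <- NULL
    best_det <- Inf
    # concentration search: random elemental starts, iterate C-steps
    for (s in seq_len(60)) {
      ix <- sample.int(n, 3)
      for (it in seq_len(30)) {
        ctr <- colMeans(pts[ix, , drop = FALSE])
        cv <- stats::cov(pts[ix, , drop = FALSE])
        dd <- tryCatch(
          stats::mahalanobis(pts, ctr, cv),
          error = function(e) rowSums(sweep(pts, 2, ctr)^2))
        if (anyNA(dd) || any(!is.finite(dd)))
          dd <- rowSums(sweep(pts, 2, ctr)^2)
        nix <- order(dd)[seq_len(h)]
        if (length(ix) == h && all(sort(nix) == sort(ix))) break
        ix <- nix
      }
      dt <- .subset_det(pts, ix)
      if (dt < best_det) {
        best_det <- dt
        best <- sort(ix)
      }
    }
  }
  est <- colMeans(pts[best, , drop = FALSE])
  structure(c(lon = est[[1]], lat = est[[2]]), subset = best)
}

#' Coordinate-wise median location
#'
#' Robust fallback used when a window holds fewer than four fixes and the
#' MCD is not computable.
#'
#' @param points Two-column matrix or data.frame of (lon, lat), `n >= 1`.
#' @return `c(lon, lat)`.
#' @export
median_location <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) stop("empty point set")
  c(lon = stats::median(pts[, 1]), lat = stats::median(pts[, 2]))
}

#' Regularize a raw track to equally spaced daily locations
#'
#' Assigns fixes to half-open windows of `step_hours` and estimates one
#' location per window: the MCD estimate when a window holds at least four
#' fixes, the coordinate-wise median for one to three fixes, and a missing
#' (`NA`) location for empty windows. The estimator used is recorded per
#' window.
#'
#' @param fixes `data.frame` of raw fixes (columns `animal_id`, `sex`,
#'   `timestamp`, `lon`, `lat`), possibly holding several animals.
#' @param step_hours Window length in hours, default 24.
#' @param anchor Optional window origin (defaults to each track's first
#'   fix).
#' @return A `data.frame` with columns `animal_id`, `sex`, `day_index`,
#'   `date`, `lon`, `lat`, `n_fixes`, `estimator` (one of `"mcd"`,
#'   `"median"`, `"missing"`).
#' @export
regularize <- function(fixes, step_hours = 24, anchor = NULL) {
  if (!is.null(fixes$animal_id) && length(unique(fixes$animal_id)) > 1) {
    out <- do.call(rbind, lapply(split(fixes, fixes$animal_id), regularize,
                                 step_hours = step_hours, anchor = anchor))
    rownames(out) <- NULL
    return(out)
  }
  if (nrow(fixes) < 2) stop("track needs at least 2 fixes")
  pw <- partition_windows(fixes, step_hours, anchor)
  if (pw$n_windows < 2)
    stop("track spans less than one full window; nothing to regularize")
  id <- if (is.null(fixes$animal_id)) "track" else fixes$animal_id[1]
  sex <- if (is.null(fixes$sex)) "unknown" else fixes$sex[1]
  K <- pw$n_windows
  lon <- lat <- rep(NA_real_, K)
  nfx <- integer(K)
  est <- rep("missing", K)
  for (k in seq_len(K)) {
    sel <- pw$index == k
    nfx[k] <- sum(sel)
    if (nfx[k] == 0) next
    pts <- cbind(fixes$lon[sel], fixes$lat[sel])
    if (nfx[k] >= 4) {
      loc <- mcd_location(pts)
      est[k] <- "mcd"
    } else {
      loc <- median_location(pts)
      est[k] <- "median"
    }
    lon[k] <- loc[[1]]
    lat[k] <- loc[[2]]
  }
  data.frame(animal_id = id, sex = sex, day_index = seq_len(K),
             date = pw$window_start + (seq_len(K) - 1) * step_hours * 3600,
             lon = lon, lat = lat, n_fixes = nfx, estimator = est,
             stringsAsFactors = FALSE)
}

#' Daily travel rates of a regularized track
#'
#' Great-circle distance between consecutive non-missing daily locations,
#' divided by the number of days between them.
#'
#' @param rtrack Regularized track `data.frame` (one animal) from
#'   [regularize()].
#' @return Numeric vector of rates in km/day, one per consecutive pair of
#'   non-missing locations, named by the later day's `day_index`.
#' @export
travel_rates <- function(rtrack) {
  obs <- which(is.finite(rtrack$lon) & is.finite(rtrack$lat))
  if (length(obs) < 2) stop("need at least two non-missing locations")
  p <- cbind(rtrack$lon[obs], rtrack$lat[obs])
  d <- gc_distance(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
  dt <- diff(rtrack$day_index[obs])
  r <- d / dt
  names(r) <- rtrack$day_index[obs][-1]
  r
}

#' Write a regularized track table to CSV
#'
#' @param rtrack Output of [regularize()].
#' @param file Output path.
#' @export
write_regularized <- function(rtrack, file) {
  utils::write.csv(rtrack, file, row.names = FALSE)
  invisible(file)
}
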