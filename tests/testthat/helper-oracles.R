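# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths: brute-force search for geometry,
# exhaustive enumeration for the robust location estimate, and a dense
# multivariate-normal likelihood for the Gaussian state-space case.

# spherical linear interpolation along the full great circle through a, b
oracle_circle_points <- function(a, b, n) {
  to_xyz <- function(p) {
    lam <- p[1] * pi / 180; phi <- p[2] * pi / 180
    c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  va <- to_xyz(a); vb <- to_xyz(b)
  om <- acos(max(-1, min(1, sum(va * vb))))
  f <- seq(0, 2 * pi / om, length.out = n)
  w1 <- sin((1 - f) * om) / sin(om)
  w2 <- sin(f * om) / sin(om)
  m <- cbind(w1 * va[1] + w2 * vb[1], w1 * va[2] + w2 * vb[2],
             w1 * va[3] + w2 * vb[3])
  m <- m / sqrt(rowSums(m^2))
  cbind(atan2(m[, 2], m[, 1]) * 180 / pi,
        asin(pmax(-1, pmin(1, m[, 3]))) * 180 / pi)
}

# minimum great-circle distance from p to the full circle through (a, b),
# by dense sampling
oracle_cross_track <- function(p, a, b, n = 1e5) {
  pts <- oracle_circle_points(a, b, n)
  min(geosphere::distHaversine(matrix(p, n, 2, byrow = TRUE), pts,
                               r = 6371))
}

# exhaustive minimal-determinant subset mean
oracle_mcd <- function(pts, h) {
  pts <- as.matrix(pts)
  subs <- utils::combn(nrow(pts), h)
  dets <- apply(subs, 2, function(ix) det(stats::cov(pts[ix, ])))
  colMeans(pts[subs[, which.min(dets)], ])
}

# exact Gaussian SSM log likelihood via the dense joint normal of y:
# x_1 ~ N(m1, P1), x_t = g x_{t-1} + w_t (w ~ N(0, s^2)), y = x + e
oracle_gauss_loglik <- function(y, g, s, se, m1 = y[1], P1 = (10 * se)^2) {
  Tt <- length(y)
  C <- matrix(0, Tt, Tt)
  # cov(x_t, x_u) = g^(t+u-2) P1 + s^2 sum_{k=2}^{min(t,u)} g^(t-k)+(u-k)
  for (t in 1:Tt) for (u in 1:Tt) {
    v <- g^(t + u - 2) * P1
    m <- min(t, u)
    if (m >= 2) {
      k <- 2:m
      v <- v + s^2 * sum(g^(t - k) * g^(u - k))
    }
    C[t, u] <- v
  }
  mu <- m1 * g^(0:(Tt - 1))
  obs <- !is.na(y)
  S <- C[obs, obs, drop = FALSE] + diag(se^2, sum(obs))
  r <- y[obs] - mu[obs]
  L <- chol(S)
  -0.5 * sum(obs) * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(backsolve(L, r, transpose = TRUE)^2)
}

# fixture builders -----------------------------------------------------------

# raw fixes for one animal moving along given daily positions, k fixes/day
make_fixes <- function(daily_lonlat, fixes_per_day = 6, noise_deg = 0,
                       id = "T1", sex = "unknown") {
  t0 <- as.POSIXct("2005-08-01 00:00:00", tz = "UTC")
  rows <- lapply(seq_len(nrow(daily_lonlat)), function(d) {
    k <- fixes_per_day
    data.frame(animal_id = id, sex = sex,
               timestamp = t0 + (d - 1) * 86400 +
                 seq(0, 86399, length.out = k),
               lon = daily_lonlat[d, 1] + rnorm(k, 0, noise_deg),
               lat = daily_lonlat[d, 2] + rnorm(k, 0, noise_deg),
               loc_class = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# quick scaled-down fit used where the test needs a real coc_fit object
quick_fit <- function(series, sex = NULL, grouping = "common", seed = 1,
                      n_iter = 800, n_burnin = 400, thin = 2, chains = 1,
                      ...) {
  suppressWarnings(coc_fit(
    series, grouping, sex = sex,
    control = coc_control(chains, n_iter, n_burnin, thin, seed = seed),
    ...))
}
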