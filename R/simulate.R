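# Synthetic data with known parameters: deviation series straight from the
# state-space model, hierarchical populations, and full Argos-like raw
# tracks so that every pipeline stage can be validated end to end.

#' Simulation design for synthetic studies
#'
#' Defaults emulate the study conditions of a southward ~3-month marine
#' migration tracked by Argos: two groups (sexes) of 7 animals, 90 daily
#' steps, strong autocorrelation of cross-track deviations (`gamma` around
#' 0.97), heavy-tailed process errors (`nu = 3`), an effective measurement
#' SD near 2 km, roughly 6 fixes per day with a small fraction of gross
#' outliers, and dwell phases of localized movement before and after the
#' migration proper.
#'
#' @param n_per_group Animals per group (groups labelled `male`/`female`).
#' @param n_days Length of each deviation series (migration days).
#' @param a,b Beta shape parameters of the (transformed) population
#'   distribution of `gamma`.
#' @param theta,tau Truncated-normal location/scale (km) of the population
#'   distribution of `sigma`.
#' @param nu Process-error degrees of freedom (`Inf` = Gaussian).
#' @param sigma_eps Measurement SD (km) added to deviation series.
#' @param gamma,sigma Optional explicit per-animal values overriding the
#'   hierarchical draws (recycled to the number of animals).
#' @param route_start,route_end Mean route endpoints `c(lon, lat)`;
#'   per-animal endpoints are jittered around these.
#' @param route_jitter_deg SD (degrees) of the endpoint jitter.
#' @param fixes_per_day Poisson mean of the number of fixes per day.
#' @param fix_noise_km Per-fix Gaussian noise SD (km per coordinate).
#' @param outlier_frac Fraction of fixes replaced by gross outliers.
#' @param outlier_km Typical displacement (km) of outlier fixes.
#' @param dwell_pre,dwell_post Days of localized pre/post-migration
#'   movement.
#' @param drift_day Migration day at which an eastward displacement ramp
#'   (a current-crossing event) begins; `NA` for none.
#' @param drift_km Total eastward displacement (km) of the drift event.
#' @param drift_duration Days over which the displacement accumulates.
#' @param seed Integer seed; all generators are reproducible given it.
#' @return List of class `"coc_sim_spec"`.
#' @export
coc_sim_spec <- function(n_per_group = 7, n_days = 90,
                         a = 120, b = 1.5, theta = 13, tau = 5, nu = 3,
                         sigma_eps = 2,
                         gamma = NULL, sigma = NULL,
                         route_start = c(-63, 44), route_end = c(-75, 15),
                         route_jitter_deg = 1.5,
                         fixes_per_day = 6, fix_noise_km = 2,
                         outlier_frac = 0.05, outlier_km = 500,
                         dwell_pre = 10, dwell_post = 10,
                         drift_day = NA, drift_km = 0, drift_duration = 5,
                         seed = NULL) {
  if (n_days < 10) stop("n_days must be at least 10")
  if (outlier_frac < 0 || outlier_frac >= 1)
    stop("outlier_frac must lie in [0, 1)")
  if (any(c(theta < 0, tau <= 0, sigma_eps < 0, fix_noise_km < 0)))
    stop("scales must be nonnegative (tau positive)")
  structure(as.list(environment()), class = "coc_sim_spec")
}

#' Simulate a deviation series from the state-space model
#'
#' `x_1` is drawn from the stationary Gaussian approximation
#' `N(0, sigma^2 / (1 - gamma^2))`, subsequent states follow the AR(1)
#' recursion with scaled-t shocks, and observations add Gaussian
#' measurement noise.
#'
#' @param gamma AR coefficient, `|gamma| < 1`.
#' @param sigma Process-error scale (km).
#' @param nu Degrees of freedom (`Inf` = Gaussian shocks).
#' @param sigma_eps Measurement SD (km).
#' @param n_days Series length (>= 2).
#' @param seed Optional seed.
#' @return List with `x` (latent states) and `y` (observations), both of
#'   length `n_days`.
#' @export
simulate_deviations <- function(gamma, sigma, nu = Inf, sigma_eps = 0,
                                n_days, seed = NULL) {
  if (abs(gamma) >= 1) stop("|gamma| must be < 1 (stationary process)")
  if (n_days < 2) stop("n_days must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n_days)
  x[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - gamma^2))
  shock <- if (is.finite(nu)) sigma * stats::rt(n_days, df = nu)
  else stats::rnorm(n_days, 0, sigma)
  for (t in 2:n_days) x[t] <- gamma * x[t - 1] + shock[t]
  y <- x + stats::rnorm(n_days, 0, sigma_eps)
  list(x = x, y = y)
}

# truncated normal on (0, Inf)
.rtnorm0 <- function(n, mean, sd) {
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  pmax(stats::qnorm(pmin(u, 1 - 1e-16), mean, sd), 1e-12)
}

#' Simulate a hierarchical population of deviation series
#'
#' Draws each animal's `(gamma_j, sigma_j)` from the population
#' distributions of the spec (or uses explicit values), simulates a
#' deviation series per animal and records the true circle of confusion.
#'
#' @param spec A [coc_sim_spec()].
#' @return List with `params` (`data.frame`: `animal_id`, `sex`, `gamma`,
#'   `sigma`, `coc_km`), `series` (named list of observed series `y`) and
#'   `states` (latent series `x`).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "coc_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  J <- 2 * spec$n_per_group
  sex <- rep(c("male", "female"), each = spec$n_per_group)
  ids <- paste0(rep(c("M", "F"), each = spec$n_per_group),
                rep(seq_len(spec$n_per_group), 2))
  gam <- if (is.null(spec$gamma))
    2 * stats::rbeta(J, spec$a, spec$b) - 1
  else rep_len(spec$gamma, J)
  sig <- if (is.null(spec$sigma)) .rtnorm0(J, spec$theta, spec$tau)
  else rep_len(spec$sigma, J)
  if (any(abs(gam) >= 1)) stop("nonstationary gamma in spec")
  series <- states <- vector("list", J)
  for (j in seq_len(J)) {
    sim <- simulate_deviations(gam[j], sig[j], spec$nu, spec$sigma_eps,
                               spec$n_days)
    series[[j]] <- sim$y
    states[[j]] <- sim$x
  }
  names(series) <- names(states) <- ids
  list(params = data.frame(animal_id = ids, sex = sex, gamma = gam,
                           sigma = sig,
                           coc_km = sig / sqrt(1 - gam^2),
                           stringsAsFactors = FALSE),
       series = series, states = states)
}

#' Simulate a full Argos-like raw track for one animal
#'
#' Builds a daily true pathway — localized pre-migration movement, a
#' migration leg along a great-circle route with the AR(1) cross-track
#' offset applied perpendicular to the route (positive = left of travel),
#' an optional eastward drift ramp, and localized post-migration movement —
#' then scatters multiple noisy fixes per day around each daily position,
#' replacing a fraction with gross outliers. Travel rate is elevated during
#' the first week after departure (a departure pulse), giving the
#' rate-based start detector a genuine peak to find.
#'
#' @param spec A [coc_sim_spec()]; per-animal fields are taken from it.
#' @param animal_id,sex Labels for the output.
#' @param gamma,sigma Per-animal process parameters (default: drawn from
#'   the spec's population distributions).
#' @param route_start,route_end Route endpoints (default: spec endpoints
#'   jittered).
#' @param seed Optional seed.
#' @return List with `fixes` (raw fix `data.frame`: `animal_id`, `sex`,
#'   `timestamp`, `lon`, `lat`, `loc_class`) and `truth` (list: `daily`
#'   `data.frame` of true positions and cross-track states, `start_day`,
#'   `end_day`, `gamma`, `sigma`, `coc_km`, `route`, and the boundary
#'   latitude of any drift event).
#' @export
simulate_argos_track <- function(spec, animal_id = "A1", sex = "unknown",
                                 gamma = NULL, sigma = NULL,
                                 route_start = NULL, route_end = NULL,
                                 seed = NULL) {
  stopifnot(inherits(spec, "coc_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gamma))
    gamma <- if (!is.null(spec$gamma)) spec$gamma[1]
    else 2 * stats::rbeta(1, spec$a, spec$b) - 1
  if (is.null(sigma))
    sigma <- if (!is.null(spec$sigma)) spec$sigma[1]
    else .rtnorm0(1, spec$theta, spec$tau)
  if (is.null(route_start))
    route_start <- spec$route_start + stats::rnorm(2, 0,
                                                   spec$route_jitter_deg)
  if (is.null(route_end))
    route_end <- spec$route_end + stats::rnorm(2, 0, spec$route_jitter_deg)
  route <- gc_route(route_start, route_end)
  Tm <- spec$n_days

  # cross-track state (km, positive = left of travel)
  x <- simulate_deviations(gamma, sigma, spec$nu, 0, Tm)$x

  # along-route progress with a departure pulse in the first week: animals
  # leave the residence area at roughly twice their cruising rate
  w <- 1 + 1.5 * exp(-(seq_len(Tm) - 1) / 5)
  frac <- c(0, cumsum(w))[seq_len(Tm)] / sum(w)
  foot <- .gc_interp(route$start, route$end, frac)
  mig <- .offset_left(foot, route$end, x)

  # eastward drift ramp (current crossing)
  drift_lat <- NA_real_
  if (is.finite(spec$drift_day) && spec$drift_km > 0) {
    ramp <- pmin(pmax((seq_len(Tm) - spec$drift_day) /
                        spec$drift_duration, 0), 1) * spec$drift_km
    deg_per_km <- 180 / (pi * EARTH_RADIUS_KM)
    mig[, 1] <- mig[, 1] + ramp * deg_per_km / cos(mig[, 2] * pi / 180)
    drift_lat <- foot[min(spec$drift_day + spec$drift_duration, Tm), 2]
  }

  # dwell phases: small-step random walks with direction churn
  rw <- function(origin, n) {
    if (n == 0) return(NULL)
    steps <- matrix(stats::rnorm(2 * n, 0, 4), n, 2)  # km/day
    deg_per_km <- 180 / (pi * EARTH_RADIUS_KM)
    pos <- apply(steps, 2, cumsum) * deg_per_km
    pos[, 1] <- pos[, 1] / cos(origin[2] * pi / 180)
    cbind(origin[1] + pos[, 1], origin[2] + pos[, 2])
  }
  pre <- rw(route$start, spec$dwell_pre)
  post <- rw(mig[Tm, ], spec$dwell_post)
  daily <- rbind(pre, mig, post)
  total <- nrow(daily)
  start_day <- spec$dwell_pre + 1L
  end_day <- spec$dwell_pre + Tm

  # fixes: Poisson count per day, jittered, with gross outliers
  t0 <- as.POSIXct("2005-08-01 00:00:00", tz = "UTC")
  deg_per_km <- 180 / (pi * EARTH_RADIUS_KM)
  rows <- vector("list", total)
  for (d in seq_len(total)) {
    nf <- stats::rpois(1, spec$fixes_per_day)
    if (nf == 0) next
    tt <- t0 + (d - 1) * 86400 + sort(stats::runif(nf, 0, 86400))
    lon <- daily[d, 1] + stats::rnorm(nf, 0, spec$fix_noise_km *
                                        deg_per_km /
                                        cos(daily[d, 2] * pi / 180))
    lat <- daily[d, 2] + stats::rnorm(nf, 0, spec$fix_noise_km *
                                        deg_per_km)
    out <- stats::runif(nf) < spec$outlier_frac
    if (any(out)) {
      k <- sum(out)
      disp <- spec$outlier_km * stats::runif(k, 0.5, 1.5)
      brg <- stats::runif(k, 0, 360)
      moved <- .gc_dest(cbind(lon[out], lat[out]), brg, disp)
      lon[out] <- moved[, 1]
      lat[out] <- moved[, 2]
    }
    rows[[d]] <- data.frame(animal_id = animal_id, sex = sex,
                            timestamp = tt, lon = lon, lat = lat,
                            loc_class = NA_character_,
                            stringsAsFactors = FALSE)
  }
  fixes <- do.call(rbind, rows)
  rownames(fixes) <- NULL
  list(fixes = fixes,
       truth = list(daily = data.frame(day = seq_len(total),
                                       lon = daily[, 1], lat = daily[, 2],
                                       x_km = c(rep(NA, spec$dwell_pre), x,
                                                rep(NA, spec$dwell_post))),
                    start_day = start_day, end_day = end_day,
                    gamma = gamma, sigma = sigma,
                    coc_km = sigma / sqrt(1 - gamma^2),
                    route = route, drift_lat = drift_lat))
}

#' Simulate a full multi-animal tracking study
#'
#' Applies [simulate_argos_track()] to every animal of the spec's two
#' groups, with per-animal parameters drawn from the population
#' distributions and per-animal jittered routes.
#'
#' @param spec A [coc_sim_spec()].
#' @return List with `fixes` (all animals' raw fixes in one `data.frame`)
#'   and `truth` (named list of per-animal truth lists).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "coc_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  J <- 2 * spec$n_per_group
  sex <- rep(c("male", "female"), each = spec$n_per_group)
  ids <- paste0(rep(c("M", "F"), each = spec$n_per_group),
                rep(seq_len(spec$n_per_group), 2))
  gam <- if (is.null(spec$gamma)) 2 * stats::rbeta(J, spec$a, spec$b) - 1
  else rep_len(spec$gamma, J)
  sig <- if (is.null(spec$sigma)) .rtnorm0(J, spec$theta, spec$tau)
  else rep_len(spec$sigma, J)
  tracks <- lapply(seq_len(J), function(j)
    simulate_argos_track(spec, animal_id = ids[j], sex = sex[j],
                         gamma = gam[j], sigma = sig[j]))
  fixes <- do.call(rbind, lapply(tracks, `[[`, "fixes"))
  rownames(fixes) <- NULL
  truth <- lapply(tracks, `[[`, "truth")
  names(truth) <- ids
  list(fixes = fixes, truth = truth)
}

#' Write the per-animal truth table of a simulated study
#'
#' @param study Output of [simulate_study()].
#' @param file Output CSV path.
#' @export
write_truth <- function(study, file) {
  tr <- study$truth
  tab <- data.frame(animal_id = names(tr),
                    gamma = vapply(tr, `[[`, 0, "gamma"),
                    sigma = vapply(tr, `[[`, 0, "sigma"),
                    coc_km = vapply(tr, `[[`, 0, "coc_km"),
                    start_day = vapply(tr, function(t) as.integer(t$start_day), 0L),
                    end_day = vapply(tr, function(t) as.integer(t$end_day), 0L))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
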