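# The synthetic-data generator: process properties, population draws, and
# the full Argos-like track pipeline.

test_that("deviation simulation is reproducible and respects degeneracies", {
  s1 <- simulate_deviations(0.9, 3, 4, 1, 50, seed = 1)
  s2 <- simulate_deviations(0.9, 3, 4, 1, 50, seed = 1)
  s3 <- simulate_deviations(0.9, 3, 4, 1, 50, seed = 2)
  expect_identical(s1, s2)
  expect_false(identical(s1$y, s3$y))
  z <- simulate_deviations(0.9, 0, Inf, 0, 20, seed = 3)
  expect_equal(z$x, rep(0, 20))
  expect_equal(z$y, rep(0, 20))
  expect_error(simulate_deviations(1, 1, Inf, 0, 10), "stationary")
})

test_that("long simulations match AR(1) theory", {
  sim <- simulate_deviations(0.98, 2, Inf, 0, 1e5, seed = 11)
  r1 <- cor(sim$x[-1], sim$x[-1e5])
  expect_lt(abs(r1 - 0.98), 0.005)
  # a 2% band on the sample variance needs a moderate gamma: the relative
  # error is ~sqrt(2 (1 + gamma) / (T (1 - gamma)))
  sim2 <- simulate_deviations(0.6, 2, Inf, 0, 1e5, seed = 11)
  expect_lt(abs(var(sim2$x) / (2^2 / (1 - 0.6^2)) - 1), 0.02)
})

test_that("population draws follow the stated hyper-distributions", {
  spec <- coc_sim_spec(n_per_group = 7, n_days = 12, seed = 13)
  pop <- simulate_population(spec)
  expect_equal(nrow(pop$params), 14)
  expect_equal(lengths(pop$series), rep(12L, 14), ignore_attr = TRUE)
  expect_equal(pop$params$coc_km,
               pop$params$sigma / sqrt(1 - pop$params$gamma^2))
  expect_equal(pop$params$sex, rep(c("male", "female"), each = 7))

  # concentration limit: a = b -> gamma near 0
  conc <- simulate_population(coc_sim_spec(n_per_group = 7, n_days = 12,
                                           a = 1e6, b = 1e6, seed = 17))
  expect_lt(max(abs(conc$params$gamma)), 0.01)

  # beta-mean identity over many draws
  big <- simulate_population(coc_sim_spec(n_per_group = 2500, n_days = 12,
                                          a = 30, b = 6, seed = 19))
  expect_equal(mean(big$params$gamma), 2 * 30 / 36 - 1, tolerance = 0.01)
})

test_that("noise-free tracks close the loop through the pipeline", {
  spec <- coc_sim_spec(n_per_group = 1, n_days = 40, gamma = 0.9, sigma = 0,
                       fixes_per_day = 1, fix_noise_km = 0,
                       outlier_frac = 0, dwell_pre = 0, dwell_post = 0)
  tr <- simulate_argos_track(spec, seed = 23)
  # Poisson fix counts leave occasional empty days; the pipeline keeps them
  rt <- regularize(tr$fixes)
  dv <- deviation_series(rt)
  expect_lt(max(abs(dv$deviation_km), na.rm = TRUE), 0.5)
})

test_that("regularization absorbs gross Argos outliers", {
  # with 6 fixes/day and a 20% outlier rate, the MCD (h = 4) succeeds when
  # at least 4 fixes are clean: P(Binom(6, 0.2) <= 2) = 0.901 bounds the
  # attainable per-day success rate
  set.seed(59)
  hits <- 0
  n_win <- 300
  for (w in seq_len(n_win)) {
    pts <- cbind(rnorm(6, -63, 0.02), rnorm(6, 40, 0.02))
    out <- runif(6) < 0.2
    if (any(out)) {
      k <- sum(out)
      moved <- cocnav:::.gc_dest(pts[out, , drop = FALSE],
                                 runif(k, 0, 360),
                                 500 * runif(k, 0.5, 1.5))
      pts[out, ] <- moved
    }
    est <- mcd_location(pts)
    hits <- hits + (gc_distance(est, c(-63, 40)) < 10)
  }
  expect_gte(hits / n_win, 0.85)

  # and through the full track pipeline, at the generator's outlier rate
  spec <- coc_sim_spec(n_per_group = 1, n_days = 30, gamma = 0.95,
                       sigma = 5, dwell_pre = 0, dwell_post = 0)
  tr <- simulate_argos_track(spec, seed = 101)
  rt <- regularize(tr$fixes)
  m <- merge(rt, tr$truth$daily, by.x = "day_index", by.y = "day")
  m <- m[is.finite(m$lon.x), ]
  d <- gc_distance(cbind(m$lon.x, m$lat.x), cbind(m$lon.y, m$lat.y))
  expect_gte(mean(d < 10), 0.85)
})

test_that("migration start is recoverable from generated tracks", {
  errs <- numeric(50)
  for (s in 1:50) {
    spec <- coc_sim_spec(n_per_group = 1, n_days = 90)
    tr <- simulate_argos_track(spec, seed = 1000 + s)
    rt <- regularize(tr$fixes)
    seg <- suppressWarnings(try(segment_migration(rt), silent = TRUE))
    errs[s] <- if (inherits(seg, "try-error")) Inf
    else seg$bounds[1] - tr$truth$start_day
  }
  # recovered within one smoother window in at least 90% of replicates
  expect_gte(mean(abs(errs) <= 7), 0.9)
})

test_that("study generation is bit-reproducible and truth is consistent", {
  spec <- coc_sim_spec(n_per_group = 2, n_days = 30, seed = 29)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  expect_identical(s1$fixes, s2$fixes)
  expect_equal(length(s1$truth), 4)
  tr <- s1$truth[[1]]
  expect_equal(tr$coc_km, tr$sigma / sqrt(1 - tr$gamma^2))
  expect_equal(tr$end_day - tr$start_day + 1L, spec$n_days)
  f <- tempfile(fileext = ".csv")
  write_truth(s1, f)
  tt <- read.csv(f)
  expect_equal(tt$animal_id, names(s1$truth))
  unlink(f)
})

test_that("drift events displace the track eastward after the ramp", {
  spec <- coc_sim_spec(n_per_group = 1, n_days = 60, gamma = 0.9,
                       sigma = 2, drift_day = 20, drift_km = 300,
                       drift_duration = 5, dwell_pre = 0, dwell_post = 0)
  tr <- simulate_argos_track(spec, seed = 31, route_start = c(-63, 44),
                             route_end = c(-75, 15))
  base <- simulate_argos_track(
    coc_sim_spec(n_per_group = 1, n_days = 60, gamma = 0.9, sigma = 2,
                 dwell_pre = 0, dwell_post = 0),
    seed = 31, route_start = c(-63, 44), route_end = c(-75, 15))
  expect_true(is.finite(tr$truth$drift_lat))
  dlon <- tr$truth$daily$lon - base$truth$daily$lon
  expect_lt(max(abs(dlon[1:19])), 1e-6)
  km_east <- dlon[40] * pi * 6371 / 180 * cos(tr$truth$daily$lat[40] *
                                                pi / 180)
  expect_equal(km_east, 300, tolerance = 1)
})
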