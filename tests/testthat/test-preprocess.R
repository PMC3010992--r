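# Window partitioning, robust daily location estimation, travel rates.

test_that("windows are half-open and conserve fixes", {
  t0 <- as.POSIXct("2005-08-01 00:00:00", tz = "UTC")
  tr <- data.frame(timestamp = t0 + c(0, 23.9, 24.0) * 3600)
  pw <- partition_windows(tr, 24)
  expect_equal(pw$index, c(1L, 1L, 2L))
  expect_equal(pw$n_windows, 2L)

  tr2 <- data.frame(timestamp = t0 + runif(37, 0, 10 * 24) * 3600)
  pw2 <- partition_windows(tr2, 24)
  expect_equal(length(pw2$index), 37L)
  expect_equal(sum(table(pw2$index)), 37L)
  expect_error(partition_windows(tr, 0), "positive")
})

test_that("median location handles singletons, odd n and outliers", {
  expect_equal(unname(median_location(rbind(c(1, 1)))), c(1, 1))
  expect_equal(unname(median_location(rbind(c(0, 0), c(1, 2), c(2, 1)))),
               c(1, 1))
  expect_equal(unname(median_location(rbind(c(0, 0), c(0, 0), c(9, 9)))),
               c(0, 0))
  expect_error(median_location(matrix(0, 0, 2)), "empty")
})

test_that("MCD equals the exhaustive minimal-determinant subset mean", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    n_out <- sample(0:max(0, n - 4), 1)
    pts <- cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05))
    if (n_out > 0)
      pts[seq_len(n_out), ] <- pts[seq_len(n_out), ] + 8
    h <- floor((n + 3) / 2)
    got <- mcd_location(pts)
    want <- oracle_mcd(pts, h)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
  expect_error(mcd_location(rbind(c(0, 0), c(1, 1), c(2, 2))), "median")
})

test_that("MCD is translation-equivariant and resists gross outliers", {
  set.seed(43)
  pts <- cbind(rnorm(8, 0, 0.1), rnorm(8, 0, 0.1))
  base <- mcd_location(pts)
  shifted <- mcd_location(sweep(pts, 2, c(3.5, -2), "+"))
  expect_equal(as.numeric(shifted), as.numeric(base) + c(3.5, -2),
               tolerance = 1e-10)

  expect_equal(as.numeric(mcd_location(matrix(c(2, 2, 2, 2, 5, 5, 5, 5),
                                              4, 2))),
               c(2, 5))

  # breakdown: n = 10, h = 7, 3 points arbitrarily far
  clean <- cbind(rnorm(7, 0, 0.1), rnorm(7, 0, 0.1))
  for (far in c(10, 1000, 1e6)) {
    pts10 <- rbind(clean, cbind(rnorm(3, far, 1), rnorm(3, far, 1)))
    est <- mcd_location(pts10, h = 7)
    expect_gte(est[1], min(clean[, 1]))
    expect_lte(est[1], max(clean[, 1]))
    expect_gte(est[2], min(clean[, 2]))
    expect_lte(est[2], max(clean[, 2]))
  }
})

test_that("concentration search is used above the exhaustive limit", {
  set.seed(47)
  pts <- rbind(cbind(rnorm(14, 0, 0.05), cbind(rnorm(14, 0, 0.05))),
               cbind(rnorm(4, 6, 0.05), rnorm(4, 6, 0.05)))
  est <- mcd_location(pts)
  expect_lt(max(abs(est)), 0.2)  # estimate stays in the main cluster
})

test_that("regularize assigns estimators per fix count and flags gaps", {
  set.seed(53)
  daily <- cbind(seq(-63, -64, length.out = 10), seq(44, 40, length.out = 10))
  fx <- make_fixes(daily, fixes_per_day = 6, noise_deg = 0.005)
  rt <- regularize(fx)
  expect_equal(nrow(rt), 10)
  expect_true(all(rt$estimator == "mcd"))
  expect_equal(rt$day_index, 1:10)

  # drop fixes on day 4 to three -> median; remove day 7 entirely -> missing
  day <- as.integer(floor(as.numeric(difftime(fx$timestamp,
                                              min(fx$timestamp),
                                              units = "hours")) / 24)) + 1L
  fx2 <- fx[!(day == 4 & seq_along(day) %in% which(day == 4)[4:6]), ]
  day2 <- as.integer(floor(as.numeric(difftime(fx2$timestamp,
                                               min(fx2$timestamp),
                                               units = "hours")) / 24)) + 1L
  fx2 <- fx2[day2 != 7, ]
  rt2 <- regularize(fx2)
  expect_equal(rt2$estimator[4], "median")
  expect_equal(rt2$estimator[7], "missing")
  expect_true(is.na(rt2$lon[7]))
  expect_equal(nrow(rt2), 10)
})

test_that("a 500 km displaced fix does not move the daily location", {
  set.seed(59)
  daily <- cbind(rep(-63, 3), rep(40, 3))
  fx <- make_fixes(daily, fixes_per_day = 5, noise_deg = 0.01)
  # displace one fix of day 2 by ~500 km
  i <- which(floor(as.numeric(difftime(fx$timestamp, min(fx$timestamp),
                                       units = "hours")) / 24) == 1)[1]
  fx$lon[i] <- fx$lon[i] + 6
  rt <- regularize(fx)
  expect_lt(gc_distance(c(rt$lon[2], rt$lat[2]), c(-63, 40)), 10)
})

test_that("travel rates match closed-form daily displacements", {
  rt <- data.frame(day_index = 1:6, lon = rep(-60, 6),
                   lat = seq(40, 35, by = -1))
  r <- travel_rates(rt)
  expect_equal(length(r), 5)
  expect_equal(unname(r), rep(2 * pi * 6371 / 360, 5), tolerance = 1e-6)

  rt$lat <- 40
  expect_equal(unname(travel_rates(rt)), rep(0, 5))

  # gap: missing day divides the displacement by the day span
  rt2 <- data.frame(day_index = 1:4, lon = rep(-60, 4),
                    lat = c(40, 39, NA, 37))
  r2 <- travel_rates(rt2)
  expect_equal(length(r2), 2)
  expect_equal(unname(r2[2]), 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_true(all(travel_rates(rt) >= 0))
})

test_that("fix reader round-trips delimited tracks", {
  fx <- make_fixes(cbind(c(-63, -63.5), c(44, 43)), fixes_per_day = 3)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(fx, f, row.names = FALSE)
  got <- read_track_fixes(f)
  expect_equal(nrow(got), 6)
  expect_s3_class(got$timestamp, "POSIXct")
  expect_equal(got$lon, fx$lon, tolerance = 1e-10)
  unlink(f)
})
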