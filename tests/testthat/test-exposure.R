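# brute-force percentile oracle: sort and interpolate at rank (n-1)*p
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  if (lo == length(s) - 1) return(s[length(s)])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

make_trip <- function(values, trip = "T1") {
  n <- length(values)
  m <- straight_stream(n = n)
  m$trip_id <- trip
  m$pm25_cal <- values
  m
}

test_that("background percentile follows the interpolation definition", {
  expect_equal(background_level(rep(8, 30)), 8)
  expect_equal(background_level(1:100, 0.10), 10.9)
  expect_equal(background_level(c(3, 5, 9), 0), 3)
  set.seed(6)
  for (k in 1:200) {
    x <- rnorm(sample(3:50, 1), 10, 3)
    p <- runif(1)
    expect_equal(background_level(x, p), percentile_oracle(x, p),
                 tolerance = 1e-12)
  }
})

test_that("trip increments are signed and consistent with the background", {
  const <- trip_exposures(make_trip(rep(8, 30)), min_points = 1)
  expect_equal(const$background, 8)
  expect_equal(const$mean_increment, 0)

  ex <- trip_exposures(make_trip(c(8, 8, 8, 12)), min_points = 1)
  expect_equal(ex$background, 8)
  expect_equal(ex$mean_increment, 1)

  pts <- point_increments(make_trip(c(8, 8, 8, 12)), ex)
  expect_equal(pts$increment, c(0, 0, 0, 4))
  # invariants: background below the maximum, exact mean identity
  expect_lte(ex$background, 12)
  expect_equal(ex$mean_increment, ex$mean_total - ex$background,
               tolerance = 1e-9)
})

test_that("trips below the minimum point count are skipped", {
  short <- trip_exposures(make_trip(rep(9, 10)), min_points = 25)
  expect_equal(nrow(short), 0)
})

test_that("increment decreases monotonically in the percentile", {
  set.seed(31)
  for (k in 1:20) {
    m <- make_trip(rlnorm(60, log(10), 0.3))
    inc <- vapply(c(0.05, 0.10, 0.15),
                  function(p) trip_exposures(m, p, min_points = 1)$mean_increment,
                  numeric(1))
    expect_true(all(diff(inc) <= 1e-12))
  }
})

test_that("unstable hours are those with large regional changes", {
  st <- flat_station(n_hours = 6)
  expect_length(stable_hours(st), 0)
  st$pm25 <- c(8, 8, 11, 11, 8.5, 8.5)  # jumps of +3 and -2.5
  ex <- stable_hours(st)
  expect_equal(ex, st$hour[3])  # only the +3 jump exceeds 2.5
  # the first hour never has a predecessor
  st2 <- flat_station(n_hours = 2)
  st2$pm25 <- c(50, 50)
  expect_length(stable_hours(st2), 0)
})

test_that("trips overlapping an excluded hour are flagged", {
  m <- make_trip(rep(9, 30))
  ex <- trip_exposures(m, min_points = 1)
  flagged <- flag_unstable_trips(ex, m, hour_floor(m$time[1]))
  expect_true(flagged$excluded_unstable_hour)
  unflagged <- flag_unstable_trips(ex, m, hour_floor(m$time[1]) + 7200)
  expect_false(unflagged$excluded_unstable_hour)
})

test_that("summaries report per-group means and histograms", {
  m1 <- make_trip(c(rep(8, 29), 68), trip = "T1")   # mean 10, increment 2.0
  ex <- trip_exposures(m1, min_points = 1)
  s <- exposure_summary(ex)
  expect_equal(s$all$mean, 2.0, tolerance = 1e-9)
  expect_equal(s$all$n, 1)
  expect_equal(sum(s$all$counts), 1)
  q <- exposure_summary(ex, by = "quarter")
  expect_named(q, "Q1")  # March trip; empty quarters are absent
})

test_that("a zero-traffic noise-free campaign yields exactly zero increments", {
  camp <- small_campaign(seed = 9, n_devices = 3, n_days = 2,
                         traffic_peak = 0, noise_sd_10s = 0,
                         rh_gain_slope = 0, background_sigma_log = 0,
                         device_gain_sd = 0, frac_flatlow_devices = 0,
                         frac_highbias_devices = 0, station_noise_sd = 0)
  fit <- analyze_campaign(camp$measurements, camp$stations,
                          colocated_devices = colocated_ids(camp))
  expect_gt(nrow(fit$exposures), 0)
  expect_equal(fit$exposures$mean_increment,
               rep(0, nrow(fit$exposures)), tolerance = 1e-12)
})
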