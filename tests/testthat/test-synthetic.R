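test_that("degenerate noise gives a constant background at the configured mean", {
  cfg <- campaign_config(ar1_coef = 0, background_sigma_log = 0, n_days = 2)
  bg <- generate_background(cfg)
  expect_equal(nrow(bg), 48)
  expect_true(all(bg$value == cfg$background_mean))
})

test_that("background generation is deterministic under the seed", {
  cfg <- campaign_config(seed = 33, n_days = 5)
  expect_identical(generate_background(cfg), generate_background(cfg))
})

test_that("long-run background mean converges to the configured mean", {
  cfg <- campaign_config(seed = 4, n_days = 365, background_mean = 9.9)
  bg <- generate_background(cfg)
  expect_equal(nrow(bg), 24 * 365)
  expect_true(all(bg$value > 0))
  # a year at moderate persistence, and a decade at the default synoptic
  # persistence, both land within 5% of the configured mean
  bg_mid <- generate_background(campaign_config(seed = 4, n_days = 365,
                                                ar1_coef = 0.5))
  expect_lt(abs(mean(bg_mid$value) - 9.9) / 9.9, 0.05)
  bg_long <- generate_background(campaign_config(seed = 4, n_days = 3650))
  expect_lt(abs(mean(bg_long$value) - 9.9) / 9.9, 0.05)
})

test_that("invalid configurations are refused", {
  expect_error(campaign_config(background_mean = -1), "background_mean")
  expect_error(campaign_config(traffic_decay_length = 0), "decay")
  expect_error(campaign_config(frac_flatlow_devices = 0.7,
                               frac_highbias_devices = 0.5), "fractions")
  expect_error(campaign_config(speed_range = c(5, 60)), "speed_range")
  expect_error(campaign_config(ar1_coef = 1), "ar1_coef")
})

test_that("traffic field follows the exponential distance decay", {
  roads <- structure(list(
    segments = list(rbind(c(0, 0), c(0, 1000))),
    busy_x = 0, busy_y = numeric(0), area_size = 1000),
    class = "road_network")
  f <- traffic_field(roads, traffic_peak = 2, decay_length = 100)
  expect_equal(f(0, 500), 2)              # on the road
  expect_equal(f(100, 500), 2 / exp(1))   # one decay length away
  f0 <- traffic_field(roads, traffic_peak = 0, decay_length = 100)
  expect_true(all(f0(c(0, 50, 500), c(0, 0, 0)) == 0))
  expect_error(traffic_field(roads, 2, -5), "positive")
})

test_that("generic polyline distances agree with the axis-aligned fast path", {
  roads <- generate_roads(campaign_config(seed = 2))
  f_fast <- traffic_field(roads, 3, 75)
  roads_slow <- roads
  roads_slow$busy_x <- NULL
  roads_slow$busy_y <- NULL
  f_slow <- traffic_field(roads_slow, 3, 75)
  set.seed(9)
  x <- runif(50, 0, 20000); y <- runif(50, 0, 20000)
  expect_equal(f_fast(x, y), f_slow(x, y), tolerance = 1e-12)
})

test_that("device roles are assigned in exact counts under the seed", {
  camp <- small_campaign(seed = 21, n_devices = 10, n_days = 2,
                         frac_flatlow_devices = 0.2,
                         frac_highbias_devices = 0.1)
  dev <- camp$truth$devices
  expect_equal(sum(dev$role == "flat_low"), 2)
  expect_equal(sum(dev$role == "high_bias"), 1)
  means <- tapply(camp$measurements$pm25_raw, camp$measurements$device_id, mean)
  flat <- dev$device_id[dev$role == "flat_low"]
  expect_true(all(means[flat] < 3))
})

test_that("noise-free zero-traffic readings equal the background exactly", {
  camp <- small_campaign(seed = 3, n_devices = 2, n_days = 2,
                         device_gain_sd = 0, rh_gain_slope = 0,
                         noise_sd_10s = 0, traffic_peak = 0,
                         frac_flatlow_devices = 0, frac_highbias_devices = 0,
                         station_noise_sd = 0)
  expect_equal(camp$measurements$pm25_raw, camp$truth$points$true_background)
})

test_that("trip durations average near the configured mean", {
  camp <- small_campaign(seed = 11, n_devices = 8, n_days = 5)
  m <- segment_trips(compute_speeds(camp$measurements))
  mobile <- m[!(m$device_id %in% colocated_ids(camp)), ]
  tt <- trip_table(mobile)
  expect_lt(abs(mean(tt$duration_s) / 60 - 17) / 17, 0.2)
})

test_that("the truth ledger is conserved and internally consistent", {
  camp <- small_campaign(seed = 5, n_devices = 4, n_days = 2)
  # one truth row per emitted measurement, in the same order
  expect_equal(nrow(camp$truth$points), nrow(camp$measurements))
  expect_identical(camp$truth$points$device_id, camp$measurements$device_id)
  expect_identical(camp$truth$points$time, camp$measurements$time)
  # per-trip truth equals the mean of its per-point truth
  per_point <- tapply(camp$truth$points$true_increment,
                      camp$truth$points$trip_id, mean)
  tr <- camp$truth$trips
  expect_equal(as.numeric(per_point[tr$trip_id]), tr$true_increment,
               tolerance = 1e-9)
  expect_true(all(camp$background$value > 0))
})

test_that("campaign files are byte-identical across runs with one seed", {
  cfg <- campaign_config(seed = 13, n_devices = 2, n_days = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_campaign(simulate_campaign(cfg), d1)
  write_campaign(simulate_campaign(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("roads survive a GeoJSON round trip", {
  camp <- small_campaign(seed = 17, n_devices = 2, n_days = 1)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_roads(camp$roads, path)
  back <- read_roads(path)
  expect_equal(length(back$segments), length(camp$roads$segments))
  f1 <- traffic_field(camp$roads, 3, 75)
  f2 <- traffic_field(back, 3, 75)
  set.seed(1)
  x <- runif(30, 0, 20000); y <- runif(30, 0, 20000)
  expect_equal(f2(x, y), f1(x, y), tolerance = 1e-3)
})

test_that("measurement CSV writing round-trips losslessly", {
  m <- straight_stream(n = 5, pm = 8.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(back$device_id, m$device_id)
  expect_equal(back$time, m$time)
  expect_equal(back$lat, m$lat)
  expect_equal(back$lon, m$lon)
  expect_equal(back$pm25_raw, m$pm25_raw)
  expect_equal(back$rh, m$rh)
  expect_equal(back$temp, m$temp)
})
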