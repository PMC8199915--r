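test_that("hourly factor reproduces the ratio mean and guard rails", {
  # symmetric ratios average to 1
  b <- hourly_beta(data.frame(c_lml = c(10, 6), c_sensors = c(8, 8)))
  expect_equal(b$beta, 1)
  expect_equal(b$guard, "applied")
  # a single station cannot calibrate the whole area
  b1 <- hourly_beta(data.frame(c_lml = 10.4, c_sensors = 8))
  expect_equal(b1$beta, 1)
  expect_equal(b1$guard, "too_few_stations")
  # clamping
  bh <- hourly_beta(data.frame(c_lml = c(48, 48), c_sensors = c(8, 8)))
  expect_equal(bh$beta, 5)
  expect_equal(bh$guard, "clamped_high")
  bl <- hourly_beta(data.frame(c_lml = c(2, 2), c_sensors = c(8, 8)))
  expect_equal(bl$beta, 0.5)
  expect_equal(bl$guard, "clamped_low")
  # high-concentration stability override: pooled 20 > 15 and the official
  # spread (sd 4) is not below 0.15 * 20 = 3
  bu <- hourly_beta(data.frame(c_lml = 20 + 4 / sqrt(2) * c(-1, 1),
                               c_sensors = c(20, 20)))
  expect_equal(sd(20 + 4 / sqrt(2) * c(-1, 1)), 4)
  expect_equal(bu$beta, 1)
  expect_equal(bu$guard, "high_conc_unstable")
  # zero sensor means are skipped and n decremented
  b0 <- hourly_beta(data.frame(c_lml = c(10, 8), c_sensors = c(0, 8)))
  expect_equal(b0$n_stations, 1)
  expect_equal(b0$guard, "too_few_stations")
})

test_that("station-hour pooling averages individual values within the radius", {
  st <- flat_station("S1", lat = 52.09, lon = 5.12, n_hours = 2)
  co <- straight_stream(device = "CO1", n = 6, speed_kmh = 0, pm = 8)
  near <- straight_stream(device = "D2", n = 6, speed_kmh = 0, pm = 10,
                          lat0 = 52.093, lon0 = 5.12)  # ~330 m away
  sh <- station_hour_sensor_means(rbind(co, near), st)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$c_sensors, 9)  # equal counts of 8s and 10s
  expect_equal(sh$n_values, 12)
  # below min_count the station-hour is absent
  sh5 <- station_hour_sensor_means(co[1:5, ], st)
  expect_equal(nrow(sh5), 0)
  far <- straight_stream(device = "D3", n = 6, pm = 99,
                         lat0 = 52.2, lon0 = 5.12)  # ~12 km away
  sh_far <- station_hour_sensor_means(rbind(co, far), st)
  expect_equal(sh_far$c_sensors, 8)
})

test_that("applying factors multiplies by the hour's beta and flags gaps", {
  m <- straight_stream(n = 3, pm = 10)
  betas <- data.frame(hour = hour_floor(m$time[1]), beta = 1.2)
  out <- apply_calibration(m, betas)
  expect_equal(out$pm25_cal, c(12, 12, 12))
  m2 <- straight_stream(n = 2, start = utc("2020-03-02 15:00:00"))
  out2 <- apply_calibration(m2, betas)
  expect_equal(out2$pm25_cal, out2$pm25_raw)
  expect_true(all(grepl("UNCALIBRATED_HOUR", out2$flags)))
})

test_that("comparison metrics match hand computation", {
  id <- comparison_metrics(c(3, 4, 5), c(3, 4, 5))
  expect_equal(id$bias, 0)
  expect_equal(id$mae, 0)
  expect_equal(id$rmse, 0)
  expect_equal(id$ci95, 0)
  h <- comparison_metrics(c(0, 2), c(1, 1))
  expect_equal(h$bias, 0)
  expect_equal(h$mae, 1)
  expect_equal(h$rmse, 1)
  expect_true(is.na(h$pearson))  # official series constant
  expect_error(comparison_metrics(1, 1), "2 paired")
})

test_that("MAE never exceeds RMSE", {
  set.seed(12)
  for (k in 1:50) {
    a <- rnorm(20, 10, 3)
    b <- rnorm(20, 10, 3)
    met <- comparison_metrics(a, b)
    expect_lte(met$mae, met$rmse + 1e-12)
    expect_gte(met$pearson, -1)
    expect_lte(met$pearson, 1)
  }
})

test_that("scaling all sensor values scales beta inversely within the rails", {
  set.seed(3)
  for (k in 1:25) {
    pairs <- data.frame(c_lml = runif(3, 6, 14), c_sensors = runif(3, 6, 14),
                        n_values = sample(6:60, 3))
    b1 <- hourly_beta(pairs)
    for (sc in c(0.8, 1.25)) {
      p2 <- pairs
      p2$c_sensors <- p2$c_sensors * sc
      b2 <- hourly_beta(p2)
      if (b1$guard == "applied" && b2$guard == "applied") {
        expect_equal(b2$beta, b1$beta / sc, tolerance = 1e-12)
      }
    }
  }
})

test_that("LSO validation is exact for perfect and common-gain sensors", {
  hours <- utc("2020-03-02 00:00:00") + 3600 * (0:47)
  bg <- 9 + 2 * sin(seq_along(hours) / 5)
  locs <- data.frame(lat = c(52.05, 52.10, 52.15), lon = c(5.05, 5.10, 5.15))
  make_case <- function(gain) {
    st <- do.call(rbind, lapply(1:3, function(s)
      data.frame(station_id = paste0("S", s), lat = locs$lat[s],
                 lon = locs$lon[s], hour = hours, pm25 = bg)))
    meas <- do.call(rbind, lapply(1:3, function(s) {
      do.call(rbind, lapply(seq_along(hours), function(h)
        data.frame(device_id = paste0("CO", s),
                   time = hours[h] + 10 * (0:5),
                   lat = locs$lat[s], lon = locs$lon[s],
                   pm25_raw = gain * bg[h], rh = 50, temp = 12,
                   speed = NA_real_, pm25_cal = NA_real_, flags = "")))
    }))
    lso_validate(meas, st)
  }
  perfect <- make_case(1)
  expect_equal(perfect$mae_lso, rep(0, 3), tolerance = 1e-12)
  expect_equal(perfect$rmse_lso, rep(0, 3), tolerance = 1e-12)
  biased <- make_case(0.85)
  expect_equal(validation_column_means(biased)[["bias_raw"]],
               -0.15 * mean(bg), tolerance = 1e-9)
  expect_equal(biased$bias_lso, rep(0, 3), tolerance = 1e-9)
  expect_error(lso_validate(straight_stream(), flat_station()), "2 stations")
})
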