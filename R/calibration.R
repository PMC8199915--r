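# Hourly ratio calibration of the sensor fleet against official reference
# stations, with guard rails, and Leave-Station-Out (LSO) cross-validation.
#
# For each hour, the correction factor is the mean over reference stations of
# the ratio official / pooled-sensor concentration, where the pooled sensor
# value combines co-located kits and passing bikes within a radius of the
# station. The factor is applied multiplicatively to every sensor record of
# that hour. Guard rails: fewer than two stations, a [0.5, 5] clamp, and a
# stability override at high concentrations when the stations disagree.

#' Pooled sensor means per station-hour
#'
#' For every station and hour, averages all calibration-eligible sensor
#' values recorded within `radius` metres of the station (co-located kits and
#' passing bikes alike; a kit inside the radius of two stations contributes
#' to both). Station-hours with fewer than `min_count` values are absent
#' from the result.
#'
#' @param measurements QC-valid measurements (positions present).
#' @param stations official station table with `station_id`, `lat`, `lon`.
#' @param radius co-location radius in metres (default 1000).
#' @param min_count minimum sensor values per station-hour (default 6).
#' @return A data frame with columns `station_id`, `hour`, `c_sensors`
#'   (pooled mean, ug/m3) and `n_values`.
#' @export
station_hour_sensor_means <- function(measurements, stations, radius = 1000,
                                      min_count = 6) {
  st <- unique(stations[, c("station_id", "lat", "lon")])
  out <- list()
  for (k in seq_len(nrow(st))) {
    d <- geosphere::distHaversine(
      cbind(measurements$lon, measurements$lat),
      c(st$lon[k], st$lat[k]))
    sel <- which(d <= radius)
    if (!length(sel)) next
    hours <- hour_floor(measurements$time[sel])
    agg <- stats::aggregate(measurements$pm25_raw[sel],
                            by = list(hour = as.numeric(hours)),
                            FUN = function(v) c(mean(v), length(v)))
    vals <- agg$x[, 1]
    cnts <- agg$x[, 2]
    ok <- cnts >= min_count
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      station_id = st$station_id[k],
      hour = as.POSIXct(agg$hour[ok], origin = "1970-01-01", tz = "UTC"),
      c_sensors = vals[ok], n_values = cnts[ok])
  }
  if (!length(out)) {
    return(data.frame(station_id = character(),
                      hour = as.POSIXct(character(), tz = "UTC"),
                      c_sensors = numeric(), n_values = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hourly correction factor from per-station pairs
#'
#' Computes the correction factor for a single hour from pairs of official
#' concentration and pooled sensor mean, applying the guard rails in fixed
#' order: raw ratio mean, fewer-than-two-stations override, clamping into
#' `beta_range`, and the high-concentration stability override (when the
#' pooled sensor mean exceeds `conc_threshold` and the across-station spread
#' of the official values is at least `sigma_frac` of their mean, the raw
#' data are kept, i.e. the factor reverts to 1).
#'
#' @param pairs data frame with one row per station: `c_lml` (official,
#'   ug/m3), `c_sensors` (pooled sensor mean, ug/m3) and optionally
#'   `n_values` (pool size, default 1). Pairs with a non-positive sensor mean
#'   are skipped and do not count towards n.
#' @param beta_range allowed factor range (default `c(0.5, 5)`).
#' @param conc_threshold pooled concentration (ug/m3) above which the
#'   stability guard is checked (default 15).
#' @param sigma_frac relative spread threshold of the stability guard
#'   (default 0.15).
#' @return A one-row data frame: `beta`, `n_stations`, `mean_lml`,
#'   `sigma_lml`, `mean_sensors` and `guard` (one of `applied`,
#'   `too_few_stations`, `clamped_low`, `clamped_high`,
#'   `high_conc_unstable`).
#' @export
hourly_beta <- function(pairs, beta_range = c(0.5, 5),
                        conc_threshold = 15, sigma_frac = 0.15) {
  if (is.null(pairs$n_values)) pairs$n_values <- 1
  pairs <- pairs[!is.na(pairs$c_lml) & !is.na(pairs$c_sensors), ]
  pairs <- pairs[pairs$c_sensors > 0, ]
  n <- nrow(pairs)
  mean_lml <- if (n) mean(pairs$c_lml) else NA_real_
  sigma_lml <- if (n >= 2) stats::sd(pairs$c_lml) else NA_real_
  mean_sensors <- if (n) {
    sum(pairs$c_sensors * pairs$n_values) / sum(pairs$n_values)
  } else NA_real_
  if (n < 2) {
    return(data.frame(beta = 1, n_stations = n, mean_lml = mean_lml,
                      sigma_lml = sigma_lml, mean_sensors = mean_sensors,
                      guard = "too_few_stations"))
  }
  beta <- mean(pairs$c_lml / pairs$c_sensors)
  guard <- "applied"
  if (beta < beta_range[1]) {
    beta <- beta_range[1]
    guard <- "clamped_low"
  } else if (beta > beta_range[2]) {
    beta <- beta_range[2]
    guard <- "clamped_high"
  }
  if (mean_sensors > conc_threshold && sigma_lml >= sigma_frac * mean_lml) {
    beta <- 1
    guard <- "high_conc_unstable"
  }
  data.frame(beta = beta, n_stations = n, mean_lml = mean_lml,
             sigma_lml = sigma_lml, mean_sensors = mean_sensors,
             guard = guard)
}

#' Hourly correction factors for a whole campaign
#'
#' Joins the pooled station-hour sensor means with the official series and
#' evaluates [hourly_beta()] for every hour with at least one pair.
#'
#' @param sensor_hours output of [station_hour_sensor_means()].
#' @param stations official station table.
#' @param ... guard-rail parameters passed to [hourly_beta()].
#' @return A data frame with one row per hour: `hour`, `beta`, `n_stations`,
#'   `mean_lml`, `sigma_lml`, `mean_sensors`, `guard`.
#' @export
hourly_betas <- function(sensor_hours, stations, ...) {
  key <- paste(stations$station_id, as.numeric(stations$hour))
  official <- stations$pm25[match(paste(sensor_hours$station_id,
                                        as.numeric(sensor_hours$hour)), key)]
  sensor_hours$c_lml <- official
  sp <- split(sensor_hours, as.numeric(sensor_hours$hour))
  rows <- lapply(sp, function(p) hourly_beta(p, ...))
  out <- do.call(rbind, rows)
  out <- cbind(hour = as.POSIXct(as.numeric(names(sp)),
                                 origin = "1970-01-01", tz = "UTC"), out)
  rownames(out) <- NULL
  out
}

#' Apply hourly correction factors to measurements
#'
#' Sets `pm25_cal = beta(hour) * pm25_raw`. Hours without a factor use 1 and
#' the affected rows are flagged `UNCALIBRATED_HOUR`.
#'
#' @param measurements a measurement data frame.
#' @param betas output of [hourly_betas()].
#' @return The data frame with `pm25_cal` filled.
#' @export
apply_calibration <- function(measurements, betas) {
  idx <- match(as.numeric(hour_floor(measurements$time)),
               as.numeric(betas$hour))
  beta <- betas$beta[idx]
  missing <- is.na(beta)
  beta[missing] <- 1
  measurements$pm25_cal <- beta * measurements$pm25_raw
  measurements$flags[missing] <- .flag_add(measurements$flags[missing],
                                           "UNCALIBRATED_HOUR")
  measurements
}

#' Agreement metrics between a sensor series and an official series
#'
#' @param sensor,official paired numeric vectors (same hours).
#' @return A list: `mean_sensor`, `mean_official`, `bias`
#'   (mean sensor - official), `mae`, `rmse`, `pearson` (NA when either
#'   series is constant), `sd_diff` (sample SD of the differences) and
#'   `ci95 = 2 * sd_diff`.
#' @export
comparison_metrics <- function(sensor, official) {
  stopifnot(length(sensor) == length(official))
  if (length(sensor) < 2) stop("at least 2 paired values required")
  d <- sensor - official
  pearson <- if (stats::sd(sensor) == 0 || stats::sd(official) == 0) {
    NA_real_
  } else {
    stats::cor(sensor, official)
  }
  sd_diff <- stats::sd(d)
  list(mean_sensor = mean(sensor), mean_official = mean(official),
       bias = mean(d), mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
       pearson = pearson, sd_diff = sd_diff, ci95 = 2 * sd_diff)
}

#' Leave-Station-Out validation of the hourly calibration
#'
#' For every station, the hourly correction factors are recomputed without
#' that station's official data and applied to the pooled sensor series at
#' the station; raw and LSO-calibrated series are then compared with the
#' official measurements.
#'
#' @param measurements calibration-eligible measurements.
#' @param stations official station table (at least two stations).
#' @param radius,min_count see [station_hour_sensor_means()].
#' @param ... guard-rail parameters passed to [hourly_beta()].
#' @return A data frame of class `lso_report`, one row per station with
#'   means, Pearson correlations, MAE, RMSE and bias for the raw and
#'   LSO-calibrated series.
#' @export
lso_validate <- function(measurements, stations, radius = 1000,
                         min_count = 6, ...) {
  st_ids <- unique(stations$station_id)
  if (length(st_ids) < 2) stop("LSO validation needs at least 2 stations")
  sensor_hours <- station_hour_sensor_means(measurements, stations,
                                            radius, min_count)
  key <- paste(stations$station_id, as.numeric(stations$hour))
  rows <- lapply(st_ids, function(s) {
    mine <- sensor_hours[sensor_hours$station_id == s, ]
    if (nrow(mine) < 2) return(NULL)
    official <- stations$pm25[match(paste(s, as.numeric(mine$hour)), key)]
    ok <- !is.na(official)
    mine <- mine[ok, ]
    official <- official[ok]
    if (nrow(mine) < 2) return(NULL)
    betas <- hourly_betas(sensor_hours[sensor_hours$station_id != s, ],
                          stations[stations$station_id != s, ], ...)
    b <- betas$beta[match(as.numeric(mine$hour), as.numeric(betas$hour))]
    b[is.na(b)] <- 1
    raw <- comparison_metrics(mine$c_sensors, official)
    lso <- comparison_metrics(b * mine$c_sensors, official)
    data.frame(station_id = s, n_hours = nrow(mine),
               mean_official = raw$mean_official,
               mean_raw = raw$mean_sensor, mean_lso = lso$mean_sensor,
               pearson_raw = raw$pearson, pearson_lso = lso$pearson,
               mae_raw = raw$mae, mae_lso = lso$mae,
               rmse_raw = raw$rmse, rmse_lso = lso$rmse,
               bias_raw = raw$bias, bias_lso = lso$bias)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no station has enough paired hours for LSO")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lso_report", "data.frame")
  out
}

#' Column means of a Leave-Station-Out report
#'
#' The across-station averages of the per-station metric columns — the
#' summary row conventionally printed under a station-by-station validation
#' table.
#'
#' @param report an `lso_report` (or any data frame with the same numeric
#'   metric columns).
#' @return A named numeric vector of column means.
#' @export
validation_column_means <- function(report) {
  cols <- c("mean_official", "mean_raw", "mean_lso", "pearson_raw",
            "pearson_lso", "mae_raw", "mae_lso", "rmse_raw", "rmse_lso",
            "bias_raw", "bias_lso")
  cols <- intersect(cols, names(report))
  colMeans(as.data.frame(report)[, cols, drop = FALSE], na.rm = TRUE)
}

#' @export
print.lso_report <- function(x, digits = 3, ...) {
  cat("Leave-Station-Out validation (", nrow(x), " stations)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("column means:\n")
  print(round(validation_column_means(x), digits))
  invisible(x)
}
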