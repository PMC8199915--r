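# End-to-end analysis: ingest -> QC -> calibration -> trip exposure -> grid.

#' Analyse a mobile PM2.5 sensor campaign
#'
#' Runs the full pipeline on raw measurement and station tables: point
#' speeds, trip segmentation, the speed-window filter, device screening
#' against the regional reference mean, hourly ratio calibration with guard
#' rails, trip trimming and the minimum-points rule, percentile background
#' subtraction per trip, the stable-hour flag, and grid aggregation of point
#' increments with suppression and quantile classes.
#'
#' @param measurements raw measurement data frame ([read_measurements()] or
#'   the `measurements` element of a [simulate_campaign()] result).
#' @param stations official station data frame ([read_stations()] or the
#'   `stations` element of a campaign).
#' @param colocated_devices ids of static sensor kits installed at reference
#'   stations; they feed calibration but are exempt from the bicycle speed
#'   filter and take no part in the trip analysis.
#' @param v_min,v_max speed window, km/h (default 5-45).
#' @param low_mean,high_ratio device screening thresholds.
#' @param gap_threshold trip segmentation gap, seconds.
#' @param trim_frac fraction trimmed off each trip end.
#' @param min_points minimum points per trip.
#' @param radius,min_count calibration co-location radius (m) and minimum
#'   sensor values per station-hour.
#' @param percentile background percentile.
#' @param stability_threshold stable-hour change threshold, ug/m3.
#' @param grid a [grid_spec()] for the exposure map.
#' @param min_obs,min_devices grid suppression thresholds.
#' @param run_lso also run Leave-Station-Out validation (default TRUE when
#'   at least two stations are present).
#' @return An object of class `pm_exposure`; see [summary.pm_exposure()].
#' @export
analyze_campaign <- function(measurements, stations,
                             colocated_devices = character(),
                             v_min = 5, v_max = 45,
                             low_mean = 3, high_ratio = 3.0,
                             gap_threshold = 120, trim_frac = 0.05,
                             min_points = 25,
                             radius = 1000, min_count = 6,
                             percentile = 0.10,
                             stability_threshold = 2.5,
                             grid = grid_spec(),
                             min_obs = 15, min_devices = 3,
                             run_lso = NULL) {
  m <- compute_speeds(measurements)
  m <- segment_trips(m, gap_threshold)
  qc <- qc_pipeline(m, stations, v_min = v_min, v_max = v_max,
                    low_mean = low_mean, high_ratio = high_ratio,
                    trim_frac = trim_frac, min_points = min_points,
                    exempt = colocated_devices)

  eligible <- qc$flagged[!.flag_has(qc$flagged$flags, "SPEED") &
                           !.flag_has(qc$flagged$flags, "DEVICE_SUSPECT"), ]
  sensor_hours <- station_hour_sensor_means(eligible, stations,
                                            radius, min_count)
  betas <- hourly_betas(sensor_hours, stations)

  clean <- apply_calibration(qc$clean, betas)
  exposures <- trip_exposures(clean, percentile, min_points)
  excluded_hours <- stable_hours(stations, stability_threshold)
  exposures <- flag_unstable_trips(exposures, clean, excluded_hours)
  increments <- point_increments(clean, exposures)

  cells <- if (nrow(increments)) {
    cc <- aggregate_cells(increments, grid, min_obs, min_devices)
    if (sum(cc$reported) >= 5) cc <- classify_cells(cc)
    cc
  } else {
    NULL
  }

  if (is.null(run_lso)) {
    run_lso <- length(unique(stations$station_id)) >= 2
  }
  lso <- if (run_lso) {
    tryCatch(lso_validate(eligible, stations, radius, min_count),
             error = function(e) NULL)
  } else NULL

  structure(list(
    measurements = clean, qc = qc, betas = betas,
    sensor_hours = sensor_hours, exposures = exposures,
    increments = increments, cells = cells, grid = grid, lso = lso,
    excluded_hours = excluded_hours,
    options = list(v_min = v_min, v_max = v_max, low_mean = low_mean,
                   high_ratio = high_ratio, gap_threshold = gap_threshold,
                   trim_frac = trim_frac, min_points = min_points,
                   radius = radius, min_count = min_count,
                   percentile = percentile,
                   stability_threshold = stability_threshold,
                   min_obs = min_obs, min_devices = min_devices)),
    class = "pm_exposure")
}

#' @export
print.pm_exposure <- function(x, ...) {
  cat("Mobile PM2.5 exposure analysis\n")
  cat(sprintf("  %d retained points in %d trips from %d devices\n",
              nrow(x$measurements), nrow(x$exposures),
              length(unique(x$exposures$device_id))))
  if (nrow(x$exposures)) {
    cat(sprintf("  mean exposure: %.2f ug/m3, mean traffic increment: %.2f ug/m3\n",
                mean(x$exposures$mean_total),
                mean(x$exposures$mean_increment)))
  }
  invisible(x)
}

#' Summarise a mobile PM2.5 exposure analysis
#'
#' @param object a `pm_exposure` from [analyze_campaign()].
#' @param ... unused.
#' @return A list with QC counts, calibration guard counts, overall and
#'   quarterly increment means, the stable-hour restricted mean, and grid
#'   cell counts; printed compactly.
#' @export
summary.pm_exposure <- function(object, ...) {
  ex <- object$exposures
  quarterly <- if (nrow(ex)) {
    tapply(ex$mean_increment, ex$quarter, mean)
  } else NULL
  stable_mean <- if (any(!ex$excluded_unstable_hour)) {
    mean(ex$mean_increment[!ex$excluded_unstable_hour])
  } else NA_real_
  out <- list(
    qc_report = object$qc$report,
    device_exclusions = table(object$qc$devices$exclusion_reason),
    beta_guards = table(object$betas$guard),
    n_trips = nrow(ex),
    mean_exposure = if (nrow(ex)) mean(ex$mean_total) else NA_real_,
    mean_increment = if (nrow(ex)) mean(ex$mean_increment) else NA_real_,
    mean_increment_stable = stable_mean,
    quarterly_increment = quarterly,
    n_cells_reported = if (!is.null(object$cells))
      sum(object$cells$reported) else 0L,
    lso_means = if (!is.null(object$lso))
      validation_column_means(object$lso) else NULL)
  class(out) <- "summary.pm_exposure"
  out
}

#' @export
print.summary.pm_exposure <- function(x, ...) {
  cat("Mobile PM2.5 exposure analysis summary\n")
  cat("QC removals:\n")
  print(x$qc_report)
  cat("device exclusions:\n")
  print(x$device_exclusions)
  cat("hourly factor guards:\n")
  print(x$beta_guards)
  cat(sprintf("trips: %d, mean exposure %.2f, mean increment %.2f ug/m3\n",
              x$n_trips, x$mean_exposure, x$mean_increment))
  cat(sprintf("mean increment, stable hours only: %.2f ug/m3\n",
              x$mean_increment_stable))
  if (!is.null(x$quarterly_increment)) {
    cat("quarterly mean increments:\n")
    print(round(x$quarterly_increment, 2))
  }
  cat(sprintf("reported grid cells: %d\n", x$n_cells_reported))
  if (!is.null(x$lso_means)) {
    cat("LSO column means:\n")
    print(round(x$lso_means, 3))
  }
  invisible(x)
}

#' Histogram of per-trip traffic increments
#'
#' @param x a `pm_exposure`.
#' @param bin bin width, ug/m3 (default 0.25).
#' @param ... passed to [graphics::hist()].
#' @export
plot.pm_exposure <- function(x, bin = 0.25, ...) {
  v <- x$exposures$mean_increment
  breaks <- seq(floor(min(v) / bin) * bin, ceiling(max(v) / bin) * bin,
                by = bin)
  graphics::hist(v, breaks = breaks,
                 xlab = "trip mean traffic increment (ug/m3)",
                 main = "Traffic-related PM2.5 along trips", ...)
}
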