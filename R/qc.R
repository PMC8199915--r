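# Validity filtering of mobile sensor streams: speed window, device-level
# screening against regional reference means, trip trimming, and the
# minimum-points rule. Filter order in the pipeline is fixed:
# speed -> device screening -> trim -> min-points.

#' Speed-window filter
#'
#' Flags measurements whose estimated speed falls outside `[v_min, v_max]`
#' km/h (bounds inclusive) with `SPEED`. Points with no speed estimate are
#' also flagged. Devices listed in `exempt` (static co-located kits at
#' reference stations) are never speed-flagged.
#'
#' @param measurements a measurement data frame with speeds computed.
#' @param v_min,v_max inclusive speed window, km/h. The defaults exclude
#'   stationary/indoor use below 5 km/h and motorised transport above
#'   45 km/h.
#' @param exempt character vector of device ids exempt from the filter.
#' @return The data frame with `SPEED` flags applied.
#' @export
speed_filter <- function(measurements, v_min = 5, v_max = 45,
                         exempt = character()) {
  bad <- is.na(measurements$speed) | measurements$speed < v_min |
    measurements$speed > v_max
  bad[measurements$device_id %in% exempt] <- FALSE
  measurements$flags[bad] <- .flag_add(measurements$flags[bad], "SPEED")
  measurements
}

# rows usable for device screening / calibration input: position present and
# not speed-flagged
.speed_valid <- function(measurements) {
  !.flag_has(measurements$flags, "SPEED") & !is.na(measurements$lat)
}

#' Per-device summaries against the regional reference mean
#'
#' For every device, computes the mean raw concentration over its speed-valid
#' points and the matched regional mean: the across-station mean of the
#' official hourly values during the hours the device was active, weighted by
#' the device's measurements in each hour.
#'
#' @param measurements a measurement data frame (speed filter applied).
#' @param stations an official station data frame ([read_stations()]).
#' @return A data frame with columns `device_id`, `n_valid`, `mean_pm25`,
#'   `matched_regional_mean`.
#' @export
device_summaries <- function(measurements, stations) {
  valid <- measurements[.speed_valid(measurements), ]
  regional <- stats::aggregate(pm25 ~ hour, data = stations, FUN = mean)
  devs <- unique(measurements$device_id)
  if (nrow(valid)) {
    hours <- hour_floor(valid$time)
    reg_at <- regional$pm25[match(as.numeric(hours),
                                  as.numeric(regional$hour))]
  }
  rows <- lapply(devs, function(d) {
    i <- which(valid$device_id == d)
    data.frame(device_id = d, n_valid = length(i),
               mean_pm25 = if (length(i)) mean(valid$pm25_raw[i]) else NA_real_,
               matched_regional_mean = if (length(i))
                 mean(reg_at[i], na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen devices for suspect data
#'
#' A device is excluded as `flat_low` when its mean concentration is below
#' `low_mean` ug/m3 (e.g. a covered sensor inlet), and as `high_outlier` when
#' its mean exceeds `high_ratio` times the regional reference mean matched to
#' its active hours. Devices with no valid points are excluded with reason
#' `empty`.
#'
#' @param summaries output of [device_summaries()].
#' @param low_mean flat-low threshold, ug/m3 (default 3).
#' @param high_ratio multiple of the matched regional mean above which a
#'   device is a high outlier (default 3).
#' @return `summaries` with an `exclusion_reason` column
#'   (`none`/`flat_low`/`high_outlier`/`empty`).
#' @export
screen_devices <- function(summaries, low_mean = 3, high_ratio = 3.0) {
  reason <- rep("none", nrow(summaries))
  reason[summaries$n_valid == 0] <- "empty"
  ok <- summaries$n_valid > 0
  reason[ok & summaries$mean_pm25 < low_mean] <- "flat_low"
  high <- ok & reason == "none" & !is.na(summaries$matched_regional_mean) &
    summaries$mean_pm25 > high_ratio * summaries$matched_regional_mean
  reason[high] <- "high_outlier"
  summaries$exclusion_reason <- reason
  summaries
}

#' Flag all measurements of excluded devices
#'
#' @param measurements a measurement data frame.
#' @param decisions output of [screen_devices()].
#' @return The data frame with `DEVICE_SUSPECT` flags applied.
#' @export
apply_device_screen <- function(measurements, decisions) {
  bad_dev <- decisions$device_id[decisions$exclusion_reason %in%
                                   c("flat_low", "high_outlier")]
  i <- measurements$device_id %in% bad_dev
  measurements$flags[i] <- .flag_add(measurements$flags[i], "DEVICE_SUSPECT")
  measurements
}

#' Trim the start and end of each trip
#'
#' Drops the first and last `floor(frac * n)` points of every trip: sensor
#' kits taken from indoors need time to equilibrate, so readings at the trip
#' edges are unreliable.
#'
#' @param measurements a measurement data frame with `trip_id`.
#' @param frac fraction trimmed off each end (default 0.05).
#' @return The data frame with edge points removed; order preserved.
#' @export
trim_trips <- function(measurements, frac = 0.05) {
  if (nrow(measurements) == 0) return(measurements)
  keep <- unlist(lapply(split(seq_len(nrow(measurements)),
                              measurements$trip_id), function(i) {
    k <- floor(frac * length(i))
    if (k == 0) return(i)
    i[seq.int(k + 1, length(i) - k)]
  }), use.names = FALSE)
  out <- measurements[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Drop trips with too few points
#'
#' @param measurements a measurement data frame with `trip_id`.
#' @param min_n minimum number of points for a trip to survive (default 25).
#' @return The data frame restricted to surviving trips.
#' @export
min_points_filter <- function(measurements, min_n = 25) {
  if (nrow(measurements) == 0) return(measurements)
  counts <- table(measurements$trip_id)
  keep_trips <- names(counts)[counts >= min_n]
  out <- measurements[measurements$trip_id %in% keep_trips, ]
  rownames(out) <- NULL
  out
}

#' Run the full QC chain on a mobile measurement table
#'
#' Applies, in order: speed window, device screening, trip trimming and the
#' minimum-points rule, and collects a removal report.
#'
#' @param measurements segmented measurements with speeds computed.
#' @param stations official station series for the regional reference.
#' @param v_min,v_max speed window, km/h.
#' @param low_mean,high_ratio device-screening thresholds.
#' @param trim_frac trip-edge trim fraction.
#' @param min_points minimum points per trip.
#' @param exempt device ids exempt from the speed filter.
#' @return A list with `clean` (surviving trip points), `flagged` (all rows
#'   with QC flags applied), `devices` (screening table) and `report`
#'   (named counts removed per rule).
#' @export
qc_pipeline <- function(measurements, stations, v_min = 5, v_max = 45,
                        low_mean = 3, high_ratio = 3.0, trim_frac = 0.05,
                        min_points = 25, exempt = character()) {
  m <- speed_filter(measurements, v_min, v_max, exempt = exempt)
  n_speed <- sum(.flag_has(m$flags, "SPEED"))
  summaries <- device_summaries(m, stations)
  decisions <- screen_devices(summaries, low_mean, high_ratio)
  m <- apply_device_screen(m, decisions)
  n_dev <- sum(.flag_has(m$flags, "DEVICE_SUSPECT") &
                 !.flag_has(m$flags, "SPEED"))
  mobile <- m[!(m$device_id %in% exempt), ]
  clean <- mobile[!.flag_has(mobile$flags, "SPEED") &
                    !.flag_has(mobile$flags, "DEVICE_SUSPECT"), ]
  n0 <- nrow(clean)
  clean <- trim_trips(clean, trim_frac)
  n_trim <- n0 - nrow(clean)
  n1 <- nrow(clean)
  clean <- min_points_filter(clean, min_points)
  n_min <- n1 - nrow(clean)
  list(clean = clean, flagged = m, devices = decisions,
       report = c(speed = n_speed, device_suspect = n_dev,
                  trimmed = n_trim, short_trip = n_min,
                  retained = nrow(clean)))
}
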