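# Reading raw measurement/station files, deriving point speeds, and
# segmenting device streams into trips.

.measurement_columns <- c("device_id", "timestamp_iso8601", "lat", "lon",
                          "pm25_raw", "rh", "temp")

.parse_time <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Read a raw mobile measurement CSV
#'
#' The dialect is comma-separated UTF-8 with a mandatory header
#' `device_id,timestamp_iso8601,lat,lon,pm25_raw,rh,temp`. Rows without a GPS
#' fix (empty lat/lon) are excluded from all downstream stages and collected
#' in the rejects report with reason `NO_POSITION`; rows with an unparseable
#' timestamp or a negative concentration are likewise rejected with a reason.
#'
#' @param path CSV file.
#' @return A data frame of measurements (columns `device_id`, `time`, `lat`,
#'   `lon`, `pm25_raw`, `rh`, `temp`, `speed`, `pm25_cal`, `flags`) with a
#'   `rejects` attribute: a data frame of rejected row numbers and reasons.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.measurement_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  time <- .parse_time(raw$timestamp_iso8601)
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  pm <- suppressWarnings(as.numeric(raw$pm25_raw))
  reasons <- rep(NA_character_, nrow(raw))
  reasons[is.na(time)] <- "BAD_TIMESTAMP"
  reasons[is.na(reasons) & (is.na(pm) | pm < 0)] <- "BAD_PM25"
  reasons[is.na(reasons) & !is.na(lat) &
            (abs(lat) > 90 | abs(lon) > 180)] <- "BAD_COORDINATES"
  reasons[is.na(reasons) & (is.na(lat) | is.na(lon))] <- "NO_POSITION"
  keep <- is.na(reasons)
  out <- data.frame(
    device_id = raw$device_id[keep], time = time[keep],
    lat = lat[keep], lon = lon[keep], pm25_raw = pm[keep],
    rh = suppressWarnings(as.numeric(raw$rh[keep])),
    temp = suppressWarnings(as.numeric(raw$temp[keep])),
    speed = NA_real_, pm25_cal = NA_real_, flags = "",
    stringsAsFactors = FALSE)
  out <- out[order(out$device_id, out$time), ]
  rownames(out) <- NULL
  attr(out, "rejects") <- data.frame(row = which(!keep),
                                     reason = reasons[!keep])
  out
}

#' Write measurements back to the CSV dialect
#'
#' Round-trips losslessly through [read_measurements()] for all dialect
#' fields (derived columns such as speed and flags are not part of the file
#' format).
#'
#' @param measurements a measurement data frame.
#' @param path output CSV file.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(measurements, path) {
  df <- data.frame(device_id = measurements$device_id,
                   timestamp_iso8601 = .fmt_time(measurements$time),
                   lat = measurements$lat, lon = measurements$lon,
                   pm25_raw = measurements$pm25_raw, rh = measurements$rh,
                   temp = measurements$temp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an official station hourly CSV
#'
#' Dialect: `station_id,lat,lon,hour_start_iso8601,pm25`.
#'
#' @param path CSV file.
#' @return A data frame with columns `station_id`, `lat`, `lon`, `hour`
#'   (POSIXct UTC hour start) and `pm25`.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lat", "lon", "hour_start_iso8601", "pm25")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(station_id = as.character(raw$station_id),
                    lat = as.numeric(raw$lat), lon = as.numeric(raw$lon),
                    hour = .parse_time(raw$hour_start_iso8601),
                    pm25 = as.numeric(raw$pm25))
  if (any(is.na(out$hour))) stop("unparseable hour in station file")
  if (any(out$pm25 < 0, na.rm = TRUE)) stop("negative station concentration")
  out
}

#' Derive point speeds from consecutive GPS fixes
#'
#' The speed at each point is the great-circle (haversine) distance to the
#' previous fix of the same device divided by the elapsed time, in km/h. The
#' first point of a device stream is assigned the speed of its successor
#' segment. Points with a repeated timestamp get flag `ZERO_DT` and no speed.
#'
#' @param measurements a measurement data frame sorted by (device, time).
#' @return The data frame with the `speed` column filled.
#' @export
compute_speeds <- function(measurements) {
  if (is.null(measurements$flags)) measurements$flags <- ""
  if (is.null(measurements$pm25_cal)) measurements$pm25_cal <- NA_real_
  m <- measurements[order(measurements$device_id, measurements$time), ]
  rownames(m) <- NULL
  n <- nrow(m)
  if (n == 0) return(m)
  same_dev <- c(FALSE, m$device_id[-1] == m$device_id[-n])
  dt <- c(NA_real_, as.numeric(diff(as.numeric(m$time))))
  dt[!same_dev] <- NA
  d <- rep(NA_real_, n)
  idx <- which(same_dev)
  if (length(idx)) {
    d[idx] <- geosphere::distHaversine(
      cbind(m$lon[idx - 1], m$lat[idx - 1]),
      cbind(m$lon[idx], m$lat[idx]))
  }
  speed <- d / dt * 3.6
  zero_dt <- same_dev & !is.na(dt) & dt == 0
  speed[zero_dt] <- NA
  # first fix of each stream inherits the successor-segment speed
  first <- which(!same_dev)
  succ <- first + 1
  ok <- succ <= n & m$device_id[pmin(succ, n)] == m$device_id[first]
  speed[first[ok]] <- speed[succ[ok]]
  m$speed <- speed
  m$flags <- ifelse(zero_dt, .flag_add(m$flags, "ZERO_DT"), m$flags)
  m
}

#' Segment device streams into trips
#'
#' A new trip starts whenever the gap between consecutive records of the same
#' device exceeds `gap_threshold` seconds. Every measurement belongs to
#' exactly one trip.
#'
#' @param measurements a measurement data frame sorted by (device, time).
#' @param gap_threshold seconds; default 120 (12 missed samples).
#' @return The data frame with a `trip_id` column (`<device>_T<number>`).
#' @export
segment_trips <- function(measurements, gap_threshold = 120) {
  m <- measurements[order(measurements$device_id, measurements$time), ]
  rownames(m) <- NULL
  n <- nrow(m)
  if (n == 0) {
    m$trip_id <- character(0)
    return(m)
  }
  same_dev <- c(FALSE, m$device_id[-1] == m$device_id[-n])
  dt <- c(Inf, as.numeric(diff(as.numeric(m$time))))
  new_trip <- !same_dev | dt > gap_threshold
  trip_num <- stats::ave(as.integer(new_trip), m$device_id, FUN = cumsum)
  m$trip_id <- sprintf("%s_T%04d", m$device_id, trip_num)
  m
}

#' Summarise trips in a segmented measurement table
#'
#' @param measurements a measurement data frame with `trip_id`.
#' @return A data frame with one row per trip: device, start/end, duration
#'   (seconds) and point count.
#' @export
trip_table <- function(measurements) {
  if (nrow(measurements) == 0) {
    return(data.frame(trip_id = character(), device_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(), n_points = integer()))
  }
  sp <- split(seq_len(nrow(measurements)), measurements$trip_id)
  rows <- lapply(names(sp), function(tid) {
    i <- sp[[tid]]
    data.frame(trip_id = tid,
               device_id = measurements$device_id[i[1]],
               start = min(measurements$time[i]),
               end = max(measurements$time[i]),
               duration_s = as.numeric(max(measurements$time[i]) -
                                         min(measurements$time[i]),
                                       units = "secs"),
               n_points = length(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# flag helpers: flags are comma-separated codes in a character column
.flag_add <- function(flags, code) {
  has <- .flag_has(flags, code)
  ifelse(has, flags, ifelse(flags == "", code, paste(flags, code, sep = ",")))
}

.flag_has <- function(flags, code) {
  vapply(strsplit(flags, ",", fixed = TRUE),
         function(f) code %in% f, logical(1))
}

#' Floor timestamps to the start of their UTC hour
#'
#' @param time a POSIXct vector.
#' @return POSIXct hour starts, UTC.
#' @export
hour_floor <- function(time) {
  as.POSIXct(floor(as.numeric(time) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}
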