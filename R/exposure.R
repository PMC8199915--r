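# Per-trip background estimation by concentration percentile and derivation
# of traffic-related PM2.5 increments, with the stable-hour exclusion and
# grouped summaries.

#' Trip background level
#'
#' A low percentile (linear-interpolation definition) of the calibrated
#' concentrations along a trip, used as the estimate of the regional
#' background during that trip: at least part of a typical trip passes
#' locations with little nearby traffic, and a percentile above the minimum
#' is robust to sensor warm-up and noise.
#'
#' @param values calibrated concentrations of one trip, ug/m3.
#' @param percentile fraction in `[0, 1]` (default 0.10).
#' @return The background estimate, ug/m3.
#' @export
background_level <- function(values, percentile = 0.10) {
  stopifnot(percentile >= 0, percentile <= 1, length(values) >= 1)
  unname(stats::quantile(values, probs = percentile, type = 7, names = FALSE))
}

#' Per-trip exposure estimates
#'
#' For every trip with at least `min_points` points, estimates the background
#' as the `percentile` of its calibrated concentrations and the mean traffic
#' increment as mean total minus background. Increments are signed (points
#' below the background estimate get negative values) so that
#' `mean_increment == mean_total - background` holds exactly.
#'
#' @param measurements QC-clean calibrated measurements with `trip_id`.
#' @param percentile background percentile (default 0.10).
#' @param min_points minimum points per trip (default 25).
#' @return A data frame with one row per trip: `trip_id`, `device_id`,
#'   `n_points`, `percentile_used`, `background`, `mean_total`,
#'   `mean_increment`, `start`, `quarter` (Q1..Q4 by calendar month) and
#'   `excluded_unstable_hour` (filled by [flag_unstable_trips()], default
#'   `FALSE`).
#' @export
trip_exposures <- function(measurements, percentile = 0.10, min_points = 25) {
  sp <- split(seq_len(nrow(measurements)), measurements$trip_id)
  rows <- lapply(names(sp), function(tid) {
    i <- sp[[tid]]
    if (length(i) < min_points) return(NULL)
    vals <- measurements$pm25_cal[i]
    bg <- background_level(vals, percentile)
    start <- min(measurements$time[i])
    data.frame(trip_id = tid, device_id = measurements$device_id[i[1]],
               n_points = length(i), percentile_used = percentile,
               background = bg, mean_total = mean(vals),
               mean_increment = mean(vals) - bg, start = start,
               quarter = paste0("Q", (as.integer(format(start, "%m")) - 1) %/% 3 + 1),
               excluded_unstable_hour = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(trip_id = character(), device_id = character(),
                      n_points = integer(), percentile_used = numeric(),
                      background = numeric(), mean_total = numeric(),
                      mean_increment = numeric(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      quarter = character(),
                      excluded_unstable_hour = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-point traffic increments
#'
#' The signed excess of each calibrated measurement over its trip's
#' background estimate.
#'
#' @param measurements QC-clean calibrated measurements with `trip_id`.
#' @param exposures output of [trip_exposures()]; trips absent from it are
#'   dropped.
#' @return A data frame with `trip_id`, `device_id`, `time`, `lat`, `lon`,
#'   `increment`.
#' @export
point_increments <- function(measurements, exposures) {
  bg <- exposures$background[match(measurements$trip_id, exposures$trip_id)]
  keep <- !is.na(bg)
  data.frame(trip_id = measurements$trip_id[keep],
             device_id = measurements$device_id[keep],
             time = measurements$time[keep],
             lat = measurements$lat[keep], lon = measurements$lon[keep],
             increment = measurements$pm25_cal[keep] - bg[keep])
}

#' Hours with unstable regional concentrations
#'
#' An hour is excluded when the across-station mean of the official
#' concentrations changed by more than `threshold` ug/m3 relative to the
#' immediately preceding hour. The first hour of a series (no predecessor)
#' is never excluded.
#'
#' @param stations official station table.
#' @param threshold change threshold, ug/m3 per hour (default 2.5).
#' @return A POSIXct vector of excluded hour starts.
#' @export
stable_hours <- function(stations, threshold = 2.5) {
  a <- stats::aggregate(pm25 ~ hour, data = stations, FUN = mean)
  a <- a[order(a$hour), ]
  if (nrow(a) < 2) return(as.POSIXct(character(), tz = "UTC"))
  dt <- as.numeric(diff(as.numeric(a$hour)))
  dv <- abs(diff(a$pm25))
  excl <- which(dt == 3600 & dv > threshold) + 1
  a$hour[excl]
}

#' Flag trips overlapping unstable hours
#'
#' A trip overlaps an excluded hour when any of its points falls in that
#' hour; such trips are omitted from sensitivity-restricted summaries.
#'
#' @param exposures output of [trip_exposures()].
#' @param measurements the trip points used to build `exposures`.
#' @param excluded POSIXct hours from [stable_hours()].
#' @return `exposures` with `excluded_unstable_hour` set.
#' @export
flag_unstable_trips <- function(exposures, measurements, excluded) {
  if (!length(excluded) || !nrow(exposures)) return(exposures)
  hrs <- as.numeric(hour_floor(measurements$time))
  bad <- measurements$trip_id[hrs %in% as.numeric(excluded)]
  exposures$excluded_unstable_hour <- exposures$trip_id %in% unique(bad)
  exposures
}

#' Summaries of trip increments
#'
#' Histogram (0.25 ug/m3 bins), mean and count of the per-trip mean traffic
#' increments, overall or by calendar quarter.
#'
#' @param exposures output of [trip_exposures()].
#' @param by `"all"` or `"quarter"`.
#' @param bin histogram bin width, ug/m3.
#' @param exclude_unstable drop trips flagged `excluded_unstable_hour`.
#' @return A list per group: `n`, `mean`, `breaks`, `counts`. Groups with no
#'   trips are absent from the result.
#' @export
exposure_summary <- function(exposures, by = c("all", "quarter"),
                             bin = 0.25, exclude_unstable = FALSE) {
  by <- match.arg(by)
  if (exclude_unstable) {
    exposures <- exposures[!exposures$excluded_unstable_hour, ]
  }
  if (!nrow(exposures)) stop("no trip exposures to summarise")
  groups <- if (by == "all") list(all = exposures) else
    split(exposures, exposures$quarter)
  lapply(groups, function(g) {
    x <- g$mean_increment
    breaks <- seq(floor(min(x) / bin) * bin, ceiling(max(x) / bin) * bin,
                  by = bin)
    if (length(breaks) < 2) breaks <- c(breaks, breaks + bin)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(n = length(x), mean = mean(x), breaks = h$breaks, counts = h$counts)
  })
}
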