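# Shared fixture builders; everything is generated in code.

utc <- function(s) as.POSIXct(s, tz = "UTC")

# a device stream moving due north at a constant speed (km/h), 10-s cadence
straight_stream <- function(device = "D1", n = 10, speed_kmh = 15,
                            start = utc("2020-03-02 10:00:00"),
                            lat0 = 52.09, lon0 = 5.12, pm = 10) {
  if (n == 0) {
    return(data.frame(device_id = character(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric(), pm25_raw = numeric(),
                      rh = numeric(), temp = numeric(), speed = numeric(),
                      pm25_cal = numeric(), flags = character(),
                      stringsAsFactors = FALSE))
  }
  step_m <- speed_kmh / 3.6 * 10
  pts <- geosphere::destPoint(c(lon0, lat0), b = 0, d = step_m * (0:(n - 1)))
  data.frame(device_id = device, time = start + 10 * (0:(n - 1)),
             lat = pts[, 2], lon = pts[, 1],
             pm25_raw = rep_len(pm, n), rh = 50, temp = 12,
             speed = NA_real_, pm25_cal = NA_real_, flags = "",
             stringsAsFactors = FALSE)
}

# a stationary hourly station series at a fixed location
flat_station <- function(station = "S1", lat = 52.09, lon = 5.12,
                         start = utc("2020-03-02 00:00:00"), n_hours = 24,
                         pm = 9) {
  data.frame(station_id = station, lat = lat, lon = lon,
             hour = start + 3600 * (0:(n_hours - 1)),
             pm25 = rep_len(pm, n_hours))
}

# identity planar projection: lon/lat are treated as metres directly,
# so grid arithmetic can be tested exactly
identity_projection <- function() {
  list(fwd = function(lon, lat) data.frame(x = lon, y = lat),
       inv = function(x, y) data.frame(lon = x, lat = y))
}

# measurement table with prescribed per-point increments in one grid cell
cell_points <- function(n, devices, x = 10, y = 10, increment = 1) {
  data.frame(trip_id = "T1", device_id = rep_len(devices, n),
             time = utc("2020-03-02 10:00:00") + 10 * (0:(n - 1)),
             lat = rep(y, n), lon = rep(x, n),
             increment = rep_len(increment, n))
}

# small campaign for end-to-end tests; moderate size keeps the suite fast
small_campaign <- function(seed = 7, n_devices = 5, n_days = 3, ...) {
  simulate_campaign(campaign_config(seed = seed, n_devices = n_devices,
                                    n_days = n_days, ...))
}

colocated_ids <- function(campaign) {
  campaign$truth$devices$device_id[campaign$truth$devices$role == "colocated"]
}
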