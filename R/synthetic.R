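# Synthetic bicycle sensor campaigns with a ground-truth ledger.
#
# The generator emulates the statistical structure the downstream analysis
# relies on: a lognormal AR(1) regional background, traffic increments that
# decay exponentially with distance to busy streets, multiplicative per-device
# gains with a humidity-dependent term, additive 10-s sensor noise,
# malfunctioning devices (flat-low and biased-high), static co-located sensor
# kits at the reference stations, and bicycle trips routed along a street grid
# with off-road start/end legs.

#' Configuration of a synthetic sensor campaign
#'
#' Builds and validates the parameter set of the campaign generator. Defaults
#' describe a month-long campaign in a 20 x 20 km study area with a regional
#' PM2.5 background around 9.9 ug/m3, near-road traffic increments of order
#' 2 ug/m3, and trips averaging 17 minutes.
#'
#' @param seed integer seed controlling every random draw of the generator.
#' @param n_devices number of bicycle sensor kits.
#' @param n_days campaign length in days.
#' @param start_date first campaign day (`Date` or "YYYY-MM-DD"), UTC.
#' @param background_mean long-run mean of the regional background, ug/m3.
#' @param background_sigma_log log-scale standard deviation of the lognormal
#'   background process (dimensionless).
#' @param ar1_coef hour-to-hour AR(1) coefficient of the log background, in
#'   `[0, 1)`. Values near 1 give synoptic (multi-day) persistence.
#' @param traffic_peak traffic increment on a busy street (`T0`), ug/m3.
#' @param traffic_decay_length e-folding distance of the increment, metres.
#' @param device_gain_mean central multiplicative gain of normal devices.
#' @param device_gain_sd log-scale spread of device gains.
#' @param rh_gain_slope relative gain change per percent relative humidity
#'   away from 50\%.
#' @param noise_sd_10s additive sensor noise per 10-s sample, ug/m3.
#' @param frac_flatlow_devices fraction of devices that malfunction flat-low.
#' @param frac_highbias_devices fraction of devices with a strong high bias.
#' @param flatlow_gain,highbias_gain gains applied to malfunctioning devices.
#' @param trip_rate_per_device_day expected trips per device per day (Poisson).
#' @param mean_trip_minutes mean trip duration, minutes.
#' @param speed_range cycling speed range (km/h) used when sampling legs.
#' @param station_locations matrix/data frame of planar station coordinates
#'   (metres, relative to the study square); default four stations spread over
#'   the central area, away from streets.
#' @param sample_period mobile sampling cadence, seconds.
#' @param area_size side of the square study area, metres.
#' @param road_spacing spacing of the street grid, metres.
#' @param busy_road_fraction probability that a street carries busy traffic.
#' @param home_spread standard deviation of trip origins around the area
#'   centre, metres (urban concentration of cyclists).
#' @param offroad_prob probability that a trip starts/ends off the street
#'   network (e.g. at a home not directly on a busy street).
#' @param colocated_period sampling cadence of the static co-located kits at
#'   reference stations, seconds.
#' @param station_noise_sd hourly measurement noise of the official stations,
#'   ug/m3.
#' @param trip_window_hours two-element vector, daily window (UTC hours) in
#'   which trips start.
#' @param rd_origin planar anchor of the study square in RD New coordinates
#'   (metres); used when writing latitude/longitude.
#'
#' @return An object of class `campaign_config` (a validated list).
#' @export
campaign_config <- function(seed = 1L,
                            n_devices = 20L,
                            n_days = 30L,
                            start_date = "2020-01-01",
                            background_mean = 9.9,
                            background_sigma_log = 0.5,
                            ar1_coef = 0.98,
                            traffic_peak = 3.5,
                            traffic_decay_length = 75,
                            device_gain_mean = 1.0,
                            device_gain_sd = 0.1,
                            rh_gain_slope = 0.003,
                            noise_sd_10s = 0.5,
                            frac_flatlow_devices = 0.15,
                            frac_highbias_devices = 0.05,
                            flatlow_gain = 0.1,
                            highbias_gain = 4.0,
                            trip_rate_per_device_day = 2,
                            mean_trip_minutes = 17,
                            speed_range = c(10, 25),
                            station_locations = NULL,
                            sample_period = 10,
                            area_size = 20000,
                            road_spacing = 500,
                            busy_road_fraction = 0.25,
                            home_spread = 2000,
                            offroad_prob = 0.8,
                            colocated_period = 30,
                            station_noise_sd = 0.4,
                            trip_window_hours = c(7, 19),
                            rd_origin = c(125000, 445000)) {
  if (is.null(station_locations)) {
    station_locations <- cbind(
      x = c(8250, 11750, 9250, 10750),
      y = c(10250, 10750, 8750, 12250))
  }
  station_locations <- as.matrix(station_locations)
  cfg <- list(
    seed = as.integer(seed), n_devices = as.integer(n_devices),
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    background_mean = background_mean,
    background_sigma_log = background_sigma_log, ar1_coef = ar1_coef,
    traffic_peak = traffic_peak,
    traffic_decay_length = traffic_decay_length,
    device_gain_mean = device_gain_mean, device_gain_sd = device_gain_sd,
    rh_gain_slope = rh_gain_slope, noise_sd_10s = noise_sd_10s,
    frac_flatlow_devices = frac_flatlow_devices,
    frac_highbias_devices = frac_highbias_devices,
    flatlow_gain = flatlow_gain, highbias_gain = highbias_gain,
    trip_rate_per_device_day = trip_rate_per_device_day,
    mean_trip_minutes = mean_trip_minutes, speed_range = speed_range,
    station_locations = station_locations, sample_period = sample_period,
    area_size = area_size, road_spacing = road_spacing,
    busy_road_fraction = busy_road_fraction, home_spread = home_spread,
    offroad_prob = offroad_prob, colocated_period = colocated_period,
    station_noise_sd = station_noise_sd,
    trip_window_hours = trip_window_hours, rd_origin = rd_origin)
  validate_campaign_config(cfg)
  class(cfg) <- "campaign_config"
  cfg
}

validate_campaign_config <- function(cfg) {
  stopifnot(cfg$n_devices >= 0, cfg$n_days >= 0)
  if (cfg$background_mean <= 0) {
    stop("background_mean must be positive")
  }
  if (cfg$traffic_decay_length <= 0) {
    stop("traffic_decay_length must be positive")
  }
  nonneg <- c("background_sigma_log", "device_gain_sd", "noise_sd_10s",
              "trip_rate_per_device_day", "station_noise_sd",
              "frac_flatlow_devices", "frac_highbias_devices")
  for (f in nonneg) {
    if (cfg[[f]] < 0) stop(sprintf("%s must be non-negative", f))
  }
  if (cfg$ar1_coef < 0 || cfg$ar1_coef >= 1) {
    stop("ar1_coef must lie in [0, 1)")
  }
  if (cfg$frac_flatlow_devices + cfg$frac_highbias_devices > 1) {
    stop("malfunctioning-device fractions exceed 1")
  }
  if (length(cfg$speed_range) != 2 || cfg$speed_range[1] <= 0 ||
      cfg$speed_range[2] > 45 || diff(cfg$speed_range) < 0) {
    stop("speed_range must be an increasing pair within (0, 45]")
  }
  invisible(cfg)
}

# hour-start timestamps of the campaign, UTC
.campaign_hours <- function(config) {
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  t0 + 3600 * (seq_len(24 * config$n_days) - 1)
}

#' Generate the hourly regional background series
#'
#' The background is the exponential of a stationary Gaussian AR(1) process on
#' the log scale, mean-corrected so that the long-run mean of the series is
#' `background_mean`. With `ar1_coef = 0` and `background_sigma_log = 0` the
#' series is constant.
#'
#' @param config a [campaign_config()].
#' @return A data frame with columns `hour` (POSIXct, UTC hour starts) and
#'   `value` (ug/m3), with `24 * n_days` rows.
#' @export
generate_background <- function(config) {
  if (config$n_days < 1) stop("n_days must be at least 1")
  validate_campaign_config(config)
  set.seed(config$seed)
  n <- 24L * config$n_days
  sig <- config$background_sigma_log
  a <- config$ar1_coef
  z <- numeric(n)
  if (sig > 0) {
    z[1] <- stats::rnorm(1, 0, sig)
    if (n > 1) {
      innov <- stats::rnorm(n - 1, 0, sig * sqrt(1 - a^2))
      for (t in 2:n) z[t] <- a * z[t - 1] + innov[t - 1]
    }
  }
  value <- exp(log(config$background_mean) - sig^2 / 2 + z)
  data.frame(hour = .campaign_hours(config), value = value)
}

#' Generate the busy-street network of the synthetic study area
#'
#' Streets form a regular grid with spacing `road_spacing` over the square
#' study area; each grid line independently carries busy traffic with
#' probability `busy_road_fraction`. Busy streets are the sources of the
#' traffic increment field; the full grid is used for routing trips.
#'
#' @param config a [campaign_config()].
#' @return An object of class `road_network`: a list with `segments` (a list
#'   of two-row coordinate matrices for the busy streets, planar metres),
#'   `busy_x`/`busy_y` (positions of busy vertical/horizontal lines),
#'   `all_x`/`all_y` (the full routing grid) and `area_size`.
#' @export
generate_roads <- function(config) {
  validate_campaign_config(config)
  set.seed(config$seed + 1L)
  s <- config$road_spacing
  pos <- seq(0, config$area_size, by = s)
  busy_v <- pos[stats::runif(length(pos)) < config$busy_road_fraction]
  busy_h <- pos[stats::runif(length(pos)) < config$busy_road_fraction]
  if (length(busy_v) + length(busy_h) == 0) busy_v <- pos[1]
  segs <- c(
    lapply(busy_v, function(x) rbind(c(x, 0), c(x, config$area_size))),
    lapply(busy_h, function(y) rbind(c(0, y), c(config$area_size, y))))
  structure(list(segments = segs, busy_x = busy_v, busy_y = busy_h,
                 all_x = pos, all_y = pos, area_size = config$area_size),
            class = "road_network")
}

# minimum distance from planar points to a set of polyline segments
.dist_to_segments <- function(px, py, segments) {
  d <- rep(Inf, length(px))
  for (seg in segments) {
    for (k in seq_len(nrow(seg) - 1)) {
      ax <- seg[k, 1]; ay <- seg[k, 2]
      bx <- seg[k + 1, 1]; by <- seg[k + 1, 2]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      if (len2 == 0) {
        d <- pmin(d, sqrt((px - ax)^2 + (py - ay)^2))
      } else {
        tt <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
        d <- pmin(d, sqrt((px - ax - tt * vx)^2 + (py - ay - tt * vy)^2))
      }
    }
  }
  d
}

#' Traffic increment field from a road network
#'
#' Returns the deterministic field `T(x) = T0 * exp(-d(x) / lambda)` where
#' `d(x)` is the planar distance from `x` to the nearest busy street.
#'
#' @param roads a `road_network` (from [generate_roads()] or [read_roads()]).
#' @param traffic_peak `T0`, the increment on a busy street, ug/m3.
#' @param decay_length `lambda`, e-folding distance in metres.
#' @return A function `(x, y) -> increment` operating on planar metres.
#' @export
traffic_field <- function(roads, traffic_peak, decay_length) {
  if (decay_length <= 0) stop("decay_length must be positive")
  if (length(roads$segments) == 0) stop("at least one road polyline required")
  has_grid <- !is.null(roads$busy_x) || !is.null(roads$busy_y)
  bx <- roads$busy_x
  by <- roads$busy_y
  segments <- roads$segments
  function(x, y) {
    if (traffic_peak == 0) return(rep(0, length(x)))
    if (has_grid) {
      # axis-aligned full-span lines admit a fast exact distance
      dx <- if (length(bx)) do.call(pmin, lapply(bx, function(v) abs(x - v))) else Inf
      dy <- if (length(by)) do.call(pmin, lapply(by, function(v) abs(y - v))) else Inf
      d <- pmin(dx, dy)
    } else {
      d <- .dist_to_segments(x, y, segments)
    }
    traffic_peak * exp(-d / decay_length)
  }
}

# relative humidity (%) as a smooth diurnal cycle, max ~04:00, min ~16:00
.diurnal_rh <- function(time) {
  hod <- (as.numeric(time) %% 86400) / 3600
  50 + 20 * cos(2 * pi * (hod - 4) / 24)
}

# piecewise-linear route of one trip: off-road access leg, walk on the
# street grid, off-road egress leg. The first and last ~20% of the walk
# prefer quiet streets (homes and destinations sit in residential areas away
# from busy traffic), the middle prefers busy arterial streets (the routes
# cyclists actually commute along) — this builds the low-traffic trip
# sections that percentile background estimation relies on into the data by
# construction. Returns a matrix of waypoints.
.trip_waypoints <- function(config, roads, target_len) {
  s <- config$road_spacing
  half <- config$area_size / 2
  quiet_margin <- min(300, 0.6 * s)
  dist_busy <- function(p) {
    dx <- if (length(roads$busy_x)) min(abs(roads$busy_x - p[1])) else Inf
    dy <- if (length(roads$busy_y)) min(abs(roads$busy_y - p[2])) else Inf
    min(dx, dy)
  }
  home <- NULL
  for (try in 1:200) {
    cand_home <- half + stats::rnorm(2, 0, config$home_spread)
    if (all(cand_home > 0.02 * config$area_size) &&
        all(cand_home < 0.98 * config$area_size)) {
      home <- cand_home
      if (dist_busy(cand_home) > quiet_margin) break
    }
  }
  node <- round(home / s) * s
  node <- pmin(pmax(node, s), config$area_size - s)
  start <- if (stats::runif(1) < config$offroad_prob) home else {
    # project the home onto the nearest street line
    if (abs(home[1] - node[1]) < abs(home[2] - node[2])) {
      c(node[1], home[2])
    } else {
      c(home[1], node[2])
    }
  }
  wps <- rbind(start, node)
  len <- sqrt(sum((node - start)^2))
  cur <- node
  dir_prev <- c(0, 0)
  dest_node <- NULL
  # whether the line traversed by a unit step from `cur` is busy
  step_busy <- function(step) {
    if (step[1] != 0) any(roads$busy_y == cur[2]) else any(roads$busy_x == cur[1])
  }
  push <- function(nxt) {
    wps <<- rbind(wps, nxt)
    len <<- len + sqrt(sum((nxt - cur)^2))
    cur <<- nxt
  }
  while (len < target_len ||
         (!is.null(dest_node) && !all(cur == dest_node) &&
            len < 1.5 * target_len)) {
    frac <- len / target_len
    if (frac > 0.88 && is.null(dest_node)) {
      # destinations, like homes, sit on quiet residential streets
      for (try in 1:50) {
        cd <- cur + sample(c(-1, 1), 2, TRUE) * sample.int(3, 2, TRUE) * s
        cd <- round(pmin(pmax(cd, s), config$area_size - s) / s) * s
        if (dist_busy(cd) > quiet_margin) { dest_node <- cd; break }
      }
      if (is.null(dest_node)) dest_node <- cur
    }
    if (!is.null(dest_node)) {
      if (all(cur == dest_node)) break
      dd <- dest_node - cur
      step <- if (abs(dd[1]) >= abs(dd[2])) c(sign(dd[1]), 0) else
        c(0, sign(dd[2]))
      push(cur + step * s)
      dir_prev <- step
      next
    }
    want_busy <- frac >= 0.12
    cand <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    cand <- Filter(function(st) !all(st == -dir_prev), cand)
    # commuters follow one arterial: keep going straight while on a busy one
    if (want_busy && any(dir_prev != 0) && step_busy(dir_prev) &&
        stats::runif(1) < 0.8) {
      nxt <- pmin(pmax(cur + dir_prev * sample.int(3, 1) * s, 0),
                  config$area_size)
      if (!all(nxt == cur)) { push(nxt); next }
    }
    pref <- Filter(function(st) step_busy(st) == want_busy, cand)
    if (length(pref)) {
      pool <- pref
    } else if (want_busy) {
      # no busy street at this node: head towards the nearest arterial
      dxv <- if (length(roads$busy_x)) min(abs(roads$busy_x - cur[1])) else Inf
      dyh <- if (length(roads$busy_y)) min(abs(roads$busy_y - cur[2])) else Inf
      towards <- if (dxv <= dyh) {
        tgt <- roads$busy_x[which.min(abs(roads$busy_x - cur[1]))]
        c(sign(tgt - cur[1]), 0)
      } else {
        tgt <- roads$busy_y[which.min(abs(roads$busy_y - cur[2]))]
        c(0, sign(tgt - cur[2]))
      }
      if (!all(towards == 0) &&
          any(vapply(cand, function(st) all(st == towards), logical(1)))) {
        # step up to, never past, the arterial
        nb <- max(1, round(min(dxv, dyh) / s))
        nxt <- pmin(pmax(cur + towards * min(sample.int(3, 1), nb) * s, 0),
                    config$area_size)
        if (!all(nxt == cur)) { push(nxt); dir_prev <- towards; next }
      }
      pool <- cand
    } else {
      pool <- cand
    }
    step <- pool[[sample.int(length(pool), 1)]]
    nxt <- pmin(pmax(cur + step * sample.int(3, 1) * s, 0), config$area_size)
    if (all(nxt == cur)) { dir_prev <- -step; next }
    push(nxt)
    dir_prev <- step
  }
  if (stats::runif(1) < config$offroad_prob) {
    # leave the network on the quiet side of the final node
    ang <- stats::runif(8, 0, 2 * pi)
    off <- stats::runif(8, 100, 300)
    cands <- cbind(cur[1] + off * cos(ang), cur[2] + off * sin(ang))
    cands <- pmin(pmax(cands, 0), config$area_size)
    db <- apply(cands, 1, dist_busy)
    wps <- rbind(wps, cands[which.max(db), ])
  }
  unname(wps)
}

# sample a waypoint path every sample_period seconds with per-leg speeds
.sample_path <- function(wps, config, duration_s) {
  nleg <- nrow(wps) - 1
  leg_len <- sqrt(rowSums((wps[-1, , drop = FALSE] -
                             wps[-nrow(wps), , drop = FALSE])^2))
  v_kmh <- stats::runif(nleg, config$speed_range[1], config$speed_range[2])
  leg_t <- leg_len / (v_kmh / 3.6)
  t_knot <- c(0, cumsum(leg_t))
  t_end <- min(duration_s, t_knot[length(t_knot)])
  tt <- seq(0, t_end, by = config$sample_period)
  if (length(tt) < 2) tt <- c(0, config$sample_period)
  keep <- t_knot[c(TRUE, leg_t > 0)]
  xk <- wps[c(TRUE, leg_t > 0), , drop = FALSE]
  x <- stats::approx(keep, xk[, 1], xout = pmin(tt, max(keep)))$y
  y <- stats::approx(keep, xk[, 2], xout = pmin(tt, max(keep)))$y
  data.frame(t_rel = tt, x = x, y = y)
}

#' Generate a complete synthetic campaign
#'
#' Draws device roles and gains, simulates bicycle trips along the street
#' network, static co-located kits at the reference stations, the official
#' hourly station series, and fills a ground-truth ledger for every emitted
#' record.
#'
#' The sensor model for a record at time t and position x is
#' `gain_d * (1 + rh_slope * (RH(t) - 50)) * (B(t) + T(x)) + N(0, noise_sd)`,
#' floored at zero (optical sensors do not report negative mass).
#'
#' @param config a [campaign_config()].
#' @return An object of class `pm_campaign`: a list with elements
#'   `measurements` (mobile + co-located records), `stations` (official hourly
#'   series), `roads`, `background`, and `truth` (list with `points`, `trips`,
#'   `devices` data frames).
#' @export
simulate_campaign <- function(config) {
  validate_campaign_config(config)
  if (config$n_devices < 1 || config$n_days < 1) {
    stop("campaign needs at least one device and one day")
  }
  background <- generate_background(config)
  roads <- generate_roads(config)
  field <- traffic_field(roads, config$traffic_peak,
                         config$traffic_decay_length)
  set.seed(config$seed + 2L)

  nd <- config$n_devices
  n_flat <- floor(config$frac_flatlow_devices * nd + 0.5)
  n_high <- floor(config$frac_highbias_devices * nd + 0.5)
  ids <- sprintf("DEV%03d", seq_len(nd))
  ord <- sample.int(nd)
  role <- rep("normal", nd)
  role[ord[seq_len(n_flat)]] <- "flat_low"
  if (n_high > 0) role[ord[n_flat + seq_len(n_high)]] <- "high_bias"
  gain <- config$device_gain_mean * exp(stats::rnorm(nd, 0, config$device_gain_sd))
  gain[role == "flat_low"] <- config$flatlow_gain
  gain[role == "high_bias"] <- config$highbias_gain

  n_stat <- nrow(config$station_locations)
  stat_ids <- sprintf("ST%02d", seq_len(n_stat))
  coloc_ids <- sprintf("CO%02d", seq_len(n_stat))
  coloc_gain <- config$device_gain_mean *
    exp(stats::rnorm(n_stat, 0, config$device_gain_sd))

  devices <- data.frame(
    device_id = c(ids, coloc_ids),
    role = c(role, rep("colocated", n_stat)),
    gain = c(gain, coloc_gain))

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  hour_index <- function(time) {
    pmax(1L, pmin(nrow(background),
                  1L + as.integer(floor(as.numeric(time - t0, units = "secs") / 3600))))
  }
  bvals <- background$value

  reading <- function(g, time, x, y, truth_inc) {
    b <- bvals[hour_index(time)]
    rh <- .diurnal_rh(time)
    raw <- g * (1 + config$rh_gain_slope * (rh - 50)) * (b + truth_inc)
    if (config$noise_sd_10s > 0) {
      raw <- raw + stats::rnorm(length(raw), 0, config$noise_sd_10s)
    }
    pmax(raw, 0)
  }

  meas <- list(); truth_pts <- list(); truth_trips <- list()
  mean_dur_s <- config$mean_trip_minutes * 60
  win <- config$trip_window_hours
  trip_counter <- stats::setNames(rep(0L, nd), ids)

  for (d in seq_len(nd)) {
    for (day in seq_len(config$n_days)) {
      ntr <- stats::rpois(1, config$trip_rate_per_device_day)
      if (ntr == 0) next
      starts <- sort(stats::runif(ntr, win[1] * 3600, win[2] * 3600))
      prev_end <- -Inf
      for (k in seq_len(ntr)) {
        dur <- stats::rgamma(1, shape = 4, rate = 4 / mean_dur_s)
        dur <- max(dur, 120)
        st <- max(starts[k], prev_end + 300)
        if (st + dur > 24 * 3600) next
        prev_end <- st + dur
        v_mean <- mean(config$speed_range) / 3.6
        wps <- .trip_waypoints(config, roads, target_len = v_mean * dur)
        path <- .sample_path(wps, config, dur)
        time <- t0 + (day - 1) * 86400 + st + path$t_rel
        inc <- field(path$x, path$y)
        pm <- reading(gain[d], time, path$x, path$y, inc)
        trip_counter[d] <- trip_counter[d] + 1L
        tid <- sprintf("%s_T%04d", ids[d], trip_counter[d])
        ll <- rd_to_wgs84(path$x + config$rd_origin[1],
                          path$y + config$rd_origin[2])
        meas[[length(meas) + 1]] <- data.frame(
          device_id = ids[d], time = time, lat = ll$lat, lon = ll$lon,
          pm25_raw = pm, rh = .diurnal_rh(time),
          temp = 12 - 6 * cos(2 * pi * (as.numeric(time) %% 86400) / 86400))
        truth_pts[[length(truth_pts) + 1]] <- data.frame(
          device_id = ids[d], time = time, trip_id = tid,
          x = path$x, y = path$y,
          true_background = bvals[hour_index(time)],
          true_increment = inc)
        truth_trips[[length(truth_trips) + 1]] <- data.frame(
          trip_id = tid, device_id = ids[d], n_points = length(inc),
          true_increment = mean(inc))
      }
    }
  }

  # static co-located kits at the stations, continuous cadence
  camp_end <- config$n_days * 86400
  for (s in seq_len(n_stat)) {
    tt <- t0 + seq(0, camp_end - config$colocated_period,
                   by = config$colocated_period)
    sx <- rep(config$station_locations[s, 1], length(tt))
    sy <- rep(config$station_locations[s, 2], length(tt))
    inc <- field(sx, sy)
    pm <- reading(coloc_gain[s], tt, sx, sy, inc)
    ll <- rd_to_wgs84(sx + config$rd_origin[1], sy + config$rd_origin[2])
    meas[[length(meas) + 1]] <- data.frame(
      device_id = coloc_ids[s], time = tt, lat = ll$lat, lon = ll$lon,
      pm25_raw = pm, rh = .diurnal_rh(tt),
      temp = 12 - 6 * cos(2 * pi * (as.numeric(tt) %% 86400) / 86400))
    truth_pts[[length(truth_pts) + 1]] <- data.frame(
      device_id = coloc_ids[s], time = tt, trip_id = NA_character_,
      x = sx, y = sy, true_background = bvals[hour_index(tt)],
      true_increment = inc)
  }

  measurements <- do.call(rbind, meas)
  o <- order(measurements$device_id, measurements$time)
  measurements <- measurements[o, ]
  rownames(measurements) <- NULL
  truth_points <- do.call(rbind, truth_pts)[o, ]
  rownames(truth_points) <- NULL
  truth_trips <- if (length(truth_trips)) do.call(rbind, truth_trips) else
    data.frame(trip_id = character(), device_id = character(),
               n_points = integer(), true_increment = numeric())

  # official hourly series: background plus station measurement noise
  stat_ll <- rd_to_wgs84(config$station_locations[, 1] + config$rd_origin[1],
                         config$station_locations[, 2] + config$rd_origin[2])
  stations <- do.call(rbind, lapply(seq_len(n_stat), function(s) {
    data.frame(station_id = stat_ids[s], lat = stat_ll$lat[s],
               lon = stat_ll$lon[s], hour = background$hour,
               pm25 = pmax(background$value +
                             stats::rnorm(nrow(background), 0,
                                          config$station_noise_sd), 0))
  }))
  rownames(stations) <- NULL

  structure(list(
    config = config, measurements = measurements, stations = stations,
    roads = roads, background = background,
    truth = list(points = truth_points, trips = truth_trips,
                 devices = devices)),
    class = "pm_campaign")
}

#' @export
print.pm_campaign <- function(x, ...) {
  cat("Synthetic mobile PM2.5 campaign\n")
  cat(sprintf("  devices: %d bikes + %d co-located kits\n",
              x$config$n_devices, nrow(x$config$station_locations)))
  cat(sprintf("  days: %d, records: %d, trips: %d\n",
              x$config$n_days, nrow(x$measurements), nrow(x$truth$trips)))
  invisible(x)
}

#' Write a synthetic campaign to CSV/GeoJSON files
#'
#' Emits the measurement and station CSV dialects consumed by
#' [read_measurements()] and [read_stations()], the ground-truth ledger, the
#' device table and the busy-street network as GeoJSON.
#'
#' @param campaign a `pm_campaign` from [simulate_campaign()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- campaign$config
  m <- campaign$measurements
  mf <- data.frame(device_id = m$device_id,
                   timestamp_iso8601 = .fmt_time(m$time),
                   lat = sprintf("%.7f", m$lat), lon = sprintf("%.7f", m$lon),
                   pm25_raw = sprintf("%.4f", m$pm25_raw),
                   rh = sprintf("%.2f", m$rh), temp = sprintf("%.2f", m$temp))
  f1 <- file.path(dir, "measurements.csv")
  utils::write.csv(mf, f1, row.names = FALSE, quote = FALSE)
  s <- campaign$stations
  sf <- data.frame(station_id = s$station_id,
                   lat = sprintf("%.7f", s$lat), lon = sprintf("%.7f", s$lon),
                   hour_start_iso8601 = .fmt_time(s$hour),
                   pm25 = sprintf("%.4f", s$pm25))
  f2 <- file.path(dir, "stations.csv")
  utils::write.csv(sf, f2, row.names = FALSE, quote = FALSE)
  tp <- campaign$truth$points
  tp$time <- .fmt_time(tp$time)
  f3 <- file.path(dir, "truth_points.csv")
  utils::write.csv(tp, f3, row.names = FALSE, quote = FALSE)
  f4 <- file.path(dir, "truth_trips.csv")
  utils::write.csv(campaign$truth$trips, f4, row.names = FALSE, quote = FALSE)
  f5 <- file.path(dir, "devices.csv")
  utils::write.csv(campaign$truth$devices, f5, row.names = FALSE, quote = FALSE)
  f6 <- file.path(dir, "roads.geojson")
  write_roads(campaign$roads, f6, rd_origin = cfg$rd_origin)
  invisible(c(f1, f2, f3, f4, f5, f6))
}

#' Write a road network as GeoJSON LineStrings
#'
#' @param roads a `road_network`.
#' @param path output file.
#' @param rd_origin planar anchor (RD New metres) used to convert the
#'   network's local coordinates to longitude/latitude.
#' @return Invisibly, `path`.
#' @export
write_roads <- function(roads, path, rd_origin = c(125000, 445000)) {
  feats <- lapply(roads$segments, function(seg) {
    ll <- rd_to_wgs84(seg[, 1] + rd_origin[1], seg[, 2] + rd_origin[2])
    list(type = "Feature", properties = list(busy = TRUE),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(seg)), function(i)
                           c(ll$lon[i], ll$lat[i]))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  invisible(path)
}

#' Read a GeoJSON road network
#'
#' Reads LineString features and converts them to planar coordinates so they
#' can drive [traffic_field()].
#'
#' @param path GeoJSON file with LineString features (WGS84 coordinates).
#' @param rd_origin planar anchor subtracted after projecting to RD New.
#' @return A `road_network` with generic polyline segments.
#' @export
read_roads <- function(path, rd_origin = c(125000, 445000)) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  segs <- lapply(gj$features, function(f) {
    if (f$geometry$type != "LineString") return(NULL)
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    xy <- wgs84_to_rd(coords[, 1], coords[, 2])
    cbind(xy$x - rd_origin[1], xy$y - rd_origin[2])
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) stop("no LineString features in ", path)
  structure(list(segments = segs, busy_x = NULL, busy_y = NULL,
                 area_size = NA_real_), class = "road_network")
}

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
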