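# Projection of point increments onto metric grids: exposure-map cells with
# small-count suppression and quantile classes, and the same-hour
# co-incidence scatter diagnostic.

#' Metric grid specification
#'
#' @param origin planar grid origin `(x0, y0)` in metres of the projected
#'   CRS (default the RD New origin `c(0, 0)`).
#' @param cell_size cell side in metres.
#' @param projection `"EPSG:28992"` (built in) or a `list(fwd =, inv =)` of
#'   functions mapping `(lon, lat) -> data.frame(x, y)` and back.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size = 25,
                      projection = "EPSG:28992") {
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(list(origin = origin, cell_size = cell_size,
                 projection = projection,
                 proj = .resolve_projection(projection)),
            class = "grid_spec")
}

#' Project points onto grid cell indices
#'
#' Cells are half-open: a point exactly on the eastern/northern edge of a
#' cell belongs to the next cell, `i = floor((x - x0) / cell)`.
#'
#' @param lat,lon point coordinates, WGS84 degrees.
#' @param grid a [grid_spec()].
#' @return A data frame with planar `x`, `y` (metres) and integer cell
#'   indices `i`, `j`.
#' @export
project_point <- function(lat, lon, grid) {
  xy <- grid$proj$fwd(lon, lat)
  i <- floor((xy$x - grid$origin[1]) / grid$cell_size)
  j <- floor((xy$y - grid$origin[2]) / grid$cell_size)
  data.frame(x = xy$x, y = xy$y, i = as.integer(i), j = as.integer(j))
}

#' Aggregate point increments onto grid cells
#'
#' Per cell: number of observations, number of distinct devices, and the
#' mean increment. A cell is `reported` only when it has at least `min_obs`
#' observations from at least `min_devices` distinct devices — the
#' small-count suppression rule of the exposure maps.
#'
#' @param increments output of [point_increments()] (needs `lat`, `lon`,
#'   `device_id`, `increment`).
#' @param grid a [grid_spec()].
#' @param min_obs minimum observations per reported cell (default 15).
#' @param min_devices minimum distinct devices per reported cell (default 3).
#' @return A data frame with `i`, `j`, `n_obs`, `n_devices`,
#'   `mean_increment`, `reported` and `quantile_class` (NA until
#'   [quantile_classes()] is applied).
#' @export
aggregate_cells <- function(increments, grid, min_obs = 15, min_devices = 3) {
  p <- project_point(increments$lat, increments$lon, grid)
  key <- paste(p$i, p$j, sep = "_")
  sp <- split(seq_len(nrow(increments)), key)
  rows <- lapply(sp, function(idx) {
    data.frame(i = p$i[idx[1]], j = p$j[idx[1]], n_obs = length(idx),
               n_devices = length(unique(increments$device_id[idx])),
               mean_increment = mean(increments$increment[idx]))
  })
  out <- do.call(rbind, rows)
  out$reported <- out$n_obs >= min_obs & out$n_devices >= min_devices
  out$quantile_class <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Quantile classes of reported cell means
#'
#' Classifies values into `k` classes, each containing (up to rounding) an
#' equal share of the values, using linear-interpolation quantile breaks.
#' Values equal to a break are assigned to the lower class; when all values
#' are identical every cell lands in class 1.
#'
#' @param x numeric values (reported cell means).
#' @param k number of classes (default 5).
#' @return Integer classes `1..k`.
#' @export
quantile_classes <- function(x, k = 5) {
  if (length(x) < k) stop("need at least k values to form k quantile classes")
  breaks <- stats::quantile(x, probs = seq_len(k - 1) / k, type = 7,
                            names = FALSE)
  as.integer(findInterval(x, breaks, left.open = TRUE) + 1L)
}

#' Classify the reported cells of an aggregation
#'
#' @param cells output of [aggregate_cells()].
#' @param k number of quantile classes.
#' @return `cells` with `quantile_class` filled for reported cells.
#' @export
classify_cells <- function(cells, k = 5) {
  rep_i <- which(cells$reported)
  cells$quantile_class[rep_i] <-
    quantile_classes(cells$mean_increment[rep_i], k)
  cells
}

#' Write reported grid cells as a GeoJSON FeatureCollection
#'
#' One Polygon per reported cell (WGS84 corner coordinates), with properties
#' `n_obs`, `n_devices`, `mean_increment` and `quantile_class`.
#'
#' @param cells output of [classify_cells()].
#' @param grid the [grid_spec()] used to build the cells.
#' @param path optional output file; when `NULL` the GeoJSON string is
#'   returned.
#' @return Invisibly `path`, or the GeoJSON string when `path` is `NULL`.
#' @export
cells_to_geojson <- function(cells, grid, path = NULL) {
  rep_cells <- cells[cells$reported, ]
  feats <- lapply(seq_len(nrow(rep_cells)), function(r) {
    i <- rep_cells$i[r]; j <- rep_cells$j[r]
    cs <- grid$cell_size
    xs <- grid$origin[1] + c(i, i + 1, i + 1, i, i) * cs
    ys <- grid$origin[2] + c(j, j, j + 1, j + 1, j) * cs
    ll <- grid$proj$inv(xs, ys)
    list(type = "Feature",
         properties = list(i = i, j = j, n_obs = rep_cells$n_obs[r],
                           n_devices = rep_cells$n_devices[r],
                           mean_increment = rep_cells$mean_increment[r],
                           quantile_class = rep_cells$quantile_class[r]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_along(xs), function(q)
                           c(ll$lon[q], ll$lat[q])))))
  })
  gj <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = 10, na = "null")
  if (is.null(path)) return(gj)
  writeLines(gj, path)
  invisible(path)
}

#' Same-hour co-incidence scatter of calibrated measurements
#'
#' A precision diagnostic for mobile use: whenever two or more devices pass
#' through the same grid cell in the same hour, the per-device means in the
#' cell are compared. Reported per (cell, hour): the across-device sample
#' standard deviation of the device means and the relative scatter
#' (SD / mean of device means).
#'
#' @param measurements calibrated measurements (`pm25_cal` set).
#' @param grid a [grid_spec()]; the conventional diagnostic uses 50 m cells.
#' @param min_devices minimum devices per cell-hour (default 2).
#' @return A data frame with `i`, `j`, `hour`, `n_devices`,
#'   `sd_across_devices`, `relative_scatter`, plus attribute
#'   `mean_relative_scatter` (campaign summary).
#' @export
coincidence_scatter <- function(measurements,
                                grid = grid_spec(cell_size = 50),
                                min_devices = 2) {
  p <- project_point(measurements$lat, measurements$lon, grid)
  hr <- hour_floor(measurements$time)
  key <- paste(p$i, p$j, as.numeric(hr), sep = "_")
  sp <- split(seq_len(nrow(measurements)), key)
  rows <- lapply(sp, function(idx) {
    devs <- measurements$device_id[idx]
    if (length(unique(devs)) < min_devices) return(NULL)
    dm <- tapply(measurements$pm25_cal[idx], devs, mean)
    s <- stats::sd(dm)
    data.frame(i = p$i[idx[1]], j = p$j[idx[1]], hour = hr[idx[1]],
               n_devices = length(dm), sd_across_devices = s,
               relative_scatter = s / mean(dm))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(),
               hour = as.POSIXct(character(), tz = "UTC"),
               n_devices = integer(), sd_across_devices = numeric(),
               relative_scatter = numeric())
  rownames(out) <- NULL
  attr(out, "mean_relative_scatter") <-
    if (nrow(out)) mean(out$relative_scatter) else NA_real_
  out
}
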