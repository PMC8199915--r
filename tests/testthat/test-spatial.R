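planar_grid <- function(origin = c(0, 0), cell_size = 25) {
  grid_spec(origin = origin, cell_size = cell_size,
            projection = identity_projection())
}

test_that("points project onto half-open cells", {
  g <- planar_grid()
  expect_equal(unlist(project_point(0, 0, g)[c("i", "j")]),
               c(i = 0, j = 0))
  expect_equal(project_point(0, 30, g)$i, 1)   # 30 m east -> cell 1
  expect_equal(project_point(0, 25, g)$i, 1)   # boundary belongs right
  expect_equal(project_point(0, 24.999, g)$i, 0)
  expect_equal(project_point(-10, -0.001, g)$j, -1)
})

test_that("projection through RD New places Utrecht points in finite cells", {
  g <- grid_spec(cell_size = 25)
  ll <- rd_to_wgs84(136010, 455010)
  p <- project_point(ll$lat, ll$lon, g)
  expect_equal(p$i, floor(136010 / 25))
  expect_equal(p$j, floor(455010 / 25))
})

test_that("aggregation applies both suppression thresholds", {
  g <- planar_grid()
  c14 <- aggregate_cells(cell_points(14, c("A", "B", "C")), g)
  expect_false(c14$reported)
  c15_2dev <- aggregate_cells(cell_points(15, c("A", "B")), g)
  expect_false(c15_2dev$reported)
  c15_3dev <- aggregate_cells(cell_points(15, c("A", "B", "C")), g)
  expect_true(c15_3dev$reported)
  expect_equal(c15_3dev$n_obs, 15)
  expect_equal(c15_3dev$n_devices, 3)
})

test_that("every increment lands in exactly one cell", {
  set.seed(14)
  pts <- data.frame(trip_id = "T", device_id = sample(LETTERS[1:5], 300, TRUE),
                    time = utc("2020-03-02 10:00:00") + 1:300,
                    lat = runif(300, 0, 500), lon = runif(300, 0, 500),
                    increment = rnorm(300))
  cells <- aggregate_cells(pts, planar_grid())
  expect_equal(sum(cells$n_obs), 300)
  # translation by one full cell shifts indices, not populations
  shifted <- aggregate_cells(pts, planar_grid(origin = c(25, 25)))
  a <- cells[order(cells$i, cells$j), ]
  b <- shifted[order(shifted$i, shifted$j), ]
  expect_equal(b$i, a$i - 1)
  expect_equal(b$j, a$j - 1)
  expect_equal(b$n_obs, a$n_obs)
})

test_that("raising suppression thresholds never reports more cells", {
  set.seed(15)
  pts <- data.frame(trip_id = "T", device_id = sample(LETTERS[1:6], 600, TRUE),
                    time = utc("2020-03-02 10:00:00") + 1:600,
                    lat = runif(600, 0, 100), lon = runif(600, 0, 100),
                    increment = rnorm(600))
  g <- planar_grid()
  n_rep <- function(mo, md) sum(aggregate_cells(pts, g, mo, md)$reported)
  base <- n_rep(15, 3)
  expect_lte(n_rep(20, 3), base)
  expect_lte(n_rep(15, 4), base)
  expect_lte(n_rep(50, 6), base)
})

test_that("quantile classes split values into equal shares", {
  expect_equal(quantile_classes(1:10, 5), rep(1:5, each = 2))
  cls <- quantile_classes(sample(1:100), 5)
  expect_equal(as.integer(table(cls)), rep(20L, 5))
  expect_equal(quantile_classes(rep(7, 9), 5), rep(1L, 9))
  expect_error(quantile_classes(1:3, 5), "at least k")
})

test_that("classified cells become valid GeoJSON polygons", {
  g <- grid_spec(cell_size = 25)
  set.seed(16)
  base <- rd_to_wgs84(136000 + runif(400, 0, 100), 455000 + runif(400, 0, 100))
  pts <- data.frame(trip_id = "T", device_id = sample(LETTERS[1:5], 400, TRUE),
                    time = utc("2020-03-02 10:00:00") + 1:400,
                    lat = base$lat, lon = base$lon,
                    increment = rnorm(400, 2))
  cells <- aggregate_cells(pts, g)
  if (sum(cells$reported) >= 5) cells <- classify_cells(cells)
  gj <- jsonlite::fromJSON(cells_to_geojson(cells, g), simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), sum(cells$reported))
  if (length(gj$features)) {
    f <- gj$features[[1]]
    expect_equal(f$geometry$type, "Polygon")
    expect_length(f$geometry$coordinates[[1]], 5)
    expect_true(all(c("n_obs", "n_devices", "mean_increment") %in%
                      names(f$properties)))
  }
})

test_that("co-incidence scatter compares device means within cell-hours", {
  same <- cell_points(20, c("A", "B"), increment = 0)
  same$pm25_cal <- 10
  cc <- coincidence_scatter(same, planar_grid(cell_size = 50))
  expect_equal(nrow(cc), 1)
  expect_equal(cc$sd_across_devices, 0)

  two <- cell_points(20, c("A", "B"))
  two$pm25_cal <- ifelse(two$device_id == "A", 8, 12)
  cc2 <- coincidence_scatter(two, planar_grid(cell_size = 50))
  expect_equal(cc2$sd_across_devices, 2.83, tolerance = 0.01)
  expect_equal(cc2$relative_scatter, 0.283, tolerance = 0.001)

  solo <- cell_points(10, "A")
  solo$pm25_cal <- 9
  expect_equal(nrow(coincidence_scatter(solo, planar_grid(cell_size = 50))), 0)
})
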