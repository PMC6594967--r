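test_that("hexagonal grid has equal-area cells matching the target", {
  g <- shared_grid()
  expect_equal(mean(g$cells$area_km2), 50000, tolerance = 0.1)
  # LAEA preserves areas exactly, so the spread is nil by construction
  expect_lt(sd(g$cells$area_km2) / mean(g$cells$area_km2), 0.1)
  # clipped cell areas reassemble the closed-form spherical box area
  bbox_area <- hexrich:::zone_area_km2(0, 90, 100, 180)
  expect_lt(
    abs(sum(g$cells$area_in_bbox_km2) - bbox_area) / bbox_area,
    0.01
  )
})

test_that("grid construction is deterministic and validates inputs", {
  g1 <- build_hex_grid(target_area_km2 = 2e5, bbox = c(0, 30, 100, 140))
  g2 <- build_hex_grid(target_area_km2 = 2e5, bbox = c(0, 30, 100, 140))
  expect_identical(g1$cells, g2$cells)
  expect_error(build_hex_grid(-1), class = "hexrich_parameter_error")
  expect_error(
    build_hex_grid(bbox = c(10, 10, 100, 100)),
    class = "hexrich_parameter_error"
  )
})

test_that("every point maps to exactly one listed cell (tiling contract)", {
  g <- shared_grid()
  set.seed(101)
  pts <- tibble::tibble(
    latitude = runif(10000, 0, 90),
    longitude = runif(10000, 100, 180)
  )
  out <- assign_to_cell(pts, g)
  expect_true(all(!is.na(out$cell_id)))
  expect_true(all(out$cell_id %in% g$cells$cell_id))
  # permuting the input permutes, but does not change, the assignment
  perm <- sample(nrow(pts))
  out2 <- assign_to_cell(pts[perm, ], g)
  expect_identical(sort(out2$cell_id), sort(out$cell_id))
})

test_that("a cell centroid is assigned to its own cell", {
  g <- shared_grid()
  inner <- g$cells[g$cells$area_in_bbox_km2 > 0.99 * g$cells$area_km2, ]
  probe <- inner[seq(1, nrow(inner), by = 25), ]
  out <- assign_to_cell(
    tibble::tibble(
      latitude = probe$centroid_lat, longitude = probe$centroid_lon
    ),
    g
  )
  expect_equal(out$cell_id, probe$cell_id)
})

test_that("band assignment is half-open with a closed top edge", {
  expect_equal(assign_band(0), 1L)
  expect_equal(assign_band(7.3), 2L)
  expect_equal(assign_band(5), 2L)
  expect_equal(assign_band(90), 18L)
  expect_error(assign_band(-1), class = "hexrich_domain_error")
  expect_error(assign_band(91), class = "hexrich_domain_error")
})

test_that("depth intervals are half-open with a closed bottom edge", {
  expect_equal(assign_depth_interval(0), 1L)
  expect_equal(assign_depth_interval(199.9), 2L)
  expect_equal(assign_depth_interval(10900), 110L)
  expect_equal(assign_depth_interval(11000), 110L)
  expect_error(assign_depth_interval(-1), class = "hexrich_domain_error")
})

test_that("band ocean areas match the closed-form zone area", {
  cs <- 30 # arcmin
  nr <- 90 * 2
  nc <- 80 * 2
  all_ocean <- env_raster(matrix(1, nr, nc), 0, 100, cs, "mask")
  # all-ocean band [0, 5): R^2 * dlambda * (sin 5 - sin 0) = 4.94e6 km2
  a1 <- band_ocean_area(1, all_ocean)
  expect_equal(a1, hexrich:::zone_area_km2(0, 5, 100, 180), tolerance = 1e-10)
  expect_equal(a1 / 4.94e6, 1, tolerance = 0.01)
  # all-land -> 0
  expect_equal(band_ocean_area(1, env_raster(matrix(0, nr, nc), 0, 100, cs)), 0)
  # checkerboard -> half the all-ocean value, within one raster cell's area
  chk <- matrix((outer(1:nr, 1:nc, "+")) %% 2, nr, nc)
  a_chk <- band_ocean_area(1, env_raster(chk, 0, 100, cs, "mask"))
  cell_area <- hexrich:::zone_area_km2(0, cs / 60, 0, cs / 60)
  expect_lt(abs(a_chk - a1 / 2), cell_area)
  # bands tile the box: areas sum to the closed-form bbox area within 1%
  tot <- sum(vapply(1:18, band_ocean_area, numeric(1), ocean_mask = all_ocean))
  bbox_area <- hexrich:::zone_area_km2(0, 90, 100, 180)
  expect_lt(abs(tot - bbox_area) / bbox_area, 0.01)
})

test_that("raster sampling is nearest-cell-centre lookup", {
  vals <- matrix(1:12, 3, 4)
  r <- env_raster(vals, 0, 100, 60, "v")
  # exact cell centres return the cell values
  expect_equal(
    sample_raster_at(data.frame(lat = 0.5, lon = 100.5), r), vals[1, 1]
  )
  expect_equal(
    sample_raster_at(data.frame(lat = 2.5, lon = 103.5), r), vals[3, 4]
  )
  # nearer A's centre than B's -> A's value
  expect_equal(
    sample_raster_at(data.frame(lat = 0.9, lon = 100.2), r), vals[1, 1]
  )
  expect_equal(
    sample_raster_at(data.frame(lat = 1.1, lon = 100.2), r), vals[2, 1]
  )
  # constant raster -> constant output
  rc <- env_raster(matrix(7, 3, 4), 0, 100, 60, "c")
  expect_equal(
    sample_raster_at(data.frame(lat = runif(20, 0, 3), lon = runif(20, 100, 104)), rc),
    rep(7, 20)
  )
  expect_error(
    sample_raster_at(data.frame(lat = 10, lon = 100.5), r),
    class = "hexrich_domain_error"
  )
})

test_that("rasters round-trip through headered gridded text", {
  m <- matrix(rnorm(12), 3, 4)
  m[2, 2] <- NA
  r <- env_raster(m, 5, 110, 30, "temperature", "degC")
  path <- withr::local_tempfile(fileext = ".txt")
  write_env_raster(r, path)
  r2 <- read_env_raster(path)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_equal(r2$origin_lat, 5)
  expect_equal(r2$origin_lon, 110)
  expect_equal(r2$cellsize_arcmin, 30)
  expect_equal(r2$variable, "temperature")
})

test_that("grid exports to GeoJSON with closed polygon rings", {
  g <- build_hex_grid(target_area_km2 = 5e5, bbox = c(0, 30, 100, 140))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_grid_geojson(g, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(g$cells))
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(length(ring), 7)
  expect_equal(ring[[1]], ring[[7]])
})
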