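test_that("world generation is deterministic and validates parameters", {
  p <- small_params()
  w1 <- generate_world(p)
  w2 <- generate_world(p)
  expect_identical(w1$species, w2$species)
  expect_identical(w1$env_rasters$temperature$values, w2$env_rasters$temperature$values)
  expect_identical(w1$effort$values, w2$effort$values)
  expect_error(
    generator_params(coupling = 2),
    class = "hexrich_parameter_error"
  )
  expect_error(
    generator_params(depth_efold = -1),
    class = "hexrich_parameter_error"
  )
  expect_error(
    generator_params(logseries_x = 1),
    class = "hexrich_parameter_error"
  )
})

test_that("effort weights sum to one over ocean and vanish on land", {
  w <- generate_world(small_params())
  eff <- w$effort$values
  ocean <- w$ocean_mask$values
  expect_equal(sum(eff), 1, tolerance = 1e-12)
  expect_true(all(eff[ocean == 0] == 0))
  expect_true(all(eff >= 0))
  # the land strip is mostly land at 60-70 N
  lat <- hexrich:::raster_lat_centers(w$ocean_mask)
  strip <- lat >= 60 & lat < 70
  expect_lt(mean(ocean[strip, ]), 0.3)
})

test_that("temperature decreases with latitude and depth; richness with depth", {
  w <- generate_world(small_params())
  tv <- w$env_rasters$temperature$values
  # strictly decreasing along every longitude column
  expect_true(all(apply(tv, 2, function(col) all(diff(col) < 0))))
  # temperature profile decreasing in depth at fixed position
  depths <- seq(0, 8000, by = 500)
  tz <- w$temperature_at(20, 150, depths)
  expect_true(all(diff(tz) < 0))
  # richness surface strictly decreasing beyond the decay onset
  z <- seq(150, 10000, by = 100)
  r <- w$richness_surface(10, 150, z)
  expect_true(all(diff(r) < 0))
  expect_true(all(w$richness_surface(runif(50, 0, 90), runif(50, 100, 180), 0) >= 0))
})

test_that("coupling couples the richness surface to temperature", {
  # coupling 1: Spearman correlation with temperature near 1 over ocean
  w1 <- generate_world(small_params(coupling = 1))
  ocean_idx <- which(w1$ocean_mask$values == 1)
  idx <- ocean_idx[seq(1, length(ocean_idx), length.out = 1000)]
  tb <- as_tibble(w1$env_rasters$temperature)
  rich <- w1$richness_surface(tb$lat[idx], tb$lon[idx], 0)
  expect_gt(cor(rich, tb$value[idx], method = "spearman"), 0.95)

  # coupling 0: richness is a pure latitude profile, independent of the
  # longitudinal temperature texture
  w0 <- generate_world(small_params(coupling = 0))
  r_a <- w0$richness_surface(rep(35, 50), seq(100, 180, length.out = 50), 0)
  expect_lt(max(abs(r_a - r_a[1])), 1e-12)
})

test_that("species ranges lie inside the study box and depths are ordered", {
  w <- generate_world(small_params())
  sp <- w$species
  expect_true(all(sp$lat_min >= 0 & sp$lat_max <= 90))
  expect_true(all(sp$lon_min >= 100 & sp$lon_max <= 180))
  expect_true(all(sp$depth_min <= sp$depth_max))
  expect_true(all(sp$depth_max <= 10900))
  expect_true(all(sp$abundance > 0))
})

test_that("log-series abundances recover the configured shape", {
  x_true <- 0.95
  draws <- withr::with_seed(3, rlogseries(5000, x_true))
  x_hat <- fit_logseries(draws)
  expect_lt(abs(x_hat - x_true) / x_true, 0.1)
})

test_that("occurrence sampling honours counts, ranges and determinism", {
  w <- generate_world(small_params())
  expect_equal(nrow(sample_occurrences(w, n_records = 0)), 0)
  occ1 <- sample_occurrences(w, n_records = 3000, seed = 5)
  occ2 <- sample_occurrences(w, n_records = 3000, seed = 5)
  expect_identical(occ1, occ2)
  expect_equal(nrow(occ1), 3000)

  # every record lies inside its species' geographic and depth range
  sp <- w$species
  i <- match(occ1$scientificName, sp$species_id)
  expect_true(all(occ1$decimalLatitude >= sp$lat_min[i] - 1e-9))
  expect_true(all(occ1$decimalLatitude <= sp$lat_max[i] + 1e-9))
  expect_true(all(occ1$decimalLongitude >= sp$lon_min[i] - 1e-9))
  expect_true(all(occ1$decimalLongitude <= sp$lon_max[i] + 1e-9))
  expect_true(all(occ1$depth >= sp$depth_min[i] - 1e-6))
  expect_true(all(occ1$depth <= sp$depth_max[i] + 1e-6))

  # all-zero effort is a generation error
  w0 <- generate_world(small_params())
  w0$effort$values[] <- 0
  expect_error(
    sample_occurrences(w0, n_records = 10),
    class = "hexrich_generation_error"
  )
})

test_that("the configured shallow fraction is reproduced", {
  w <- generate_world(small_params(n_species = 600))
  occ <- sample_occurrences(w, n_records = 20000, seed = 8)
  expect_equal(mean(occ$depth <= 500), 0.83, tolerance = 0.015)
})

test_that("uniform effort and richness give near-uniform cell counts", {
  # flat latitude profile, no hotspots, small all-ocean box of 100 cells
  p <- generator_params(
    bbox = c(10, 20, 110, 120), cell_size_arcmin = 60,
    n_species = 200, n_records = 20000,
    lat_peak_primary_amp = 0, lat_peak_secondary_amp = 0, eq_dip_amp = 0,
    n_hotspots = 0, land_strip = c(89, 90), land_strip_lon_max = 100,
    records_per_sample = 1.01,
    seed = 21
  )
  w <- generate_world(p)
  expect_equal(dim(w$effort$values), c(10, 10))
  occ <- sample_occurrences(w, seed = 22)
  cellidx <- paste(floor(occ$decimalLatitude), floor(occ$decimalLongitude))
  counts <- table(cellidx)
  expect_equal(length(counts), 100)
  expect_lt(sd(counts) / mean(counts), 0.15)
})

test_that("worlds round-trip their rasters and truth summary to disk", {
  w <- generate_world(small_params(n_species = 50))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "env_temperature.txt")))
  expect_true(file.exists(file.path(dir, "ocean_mask.txt")))
  r <- read_env_raster(file.path(dir, "env_temperature.txt"))
  expect_equal(r$values, w$env_rasters$temperature$values, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$n_species, 50)
})
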