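# Shared fixtures, built in code.

# Small occurrence tibble in internal form.
make_records <- function(species, lat, lon, depth = NA_real_,
                         date = as.Date("2010-06-01")) {
  n <- length(species)
  tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    raw_name = species,
    accepted_name = NA_character_,
    species = species,
    latitude = rep_len(lat, n),
    longitude = rep_len(lon, n),
    depth = rep_len(depth, n),
    event_date = rep_len(date, n),
    dataset_id = "test",
    flags = ""
  )
}

# Incidence structure from a list of per-sample species vectors.
inc_from_sets <- function(sets) {
  recs <- purrr::imap(sets, function(spp, i) {
    make_records(
      spp,
      lat = 10 + i, lon = 120 + i,
      date = as.Date("2010-01-01") + i
    )
  }) |> purrr::list_rbind()
  incidence_summary(recs)
}

# Exhaustive rarefaction oracle: mean species count over all C(N, m)
# subsets of the samples.
enumerate_rarefaction <- function(sets, m) {
  n <- length(sets)
  combos <- utils::combn(n, m, simplify = FALSE)
  mean(vapply(
    combos,
    function(ix) length(unique(unlist(sets[ix]))),
    numeric(1)
  ))
}

# A small world: coarse rasters, modest pool, kept cheap for unit tests.
small_params <- function(...) {
  args <- utils::modifyList(
    list(
      cell_size_arcmin = 60, n_species = 300, n_records = 4000,
      seed = 42
    ),
    list(...)
  )
  do.call(hexrich::generator_params, args)
}

# The well-sampled survey-network configuration used for the recovery
# experiments: many repeat-station hotspots so that hundreds of hexagons
# accumulate the >= 50 samples ES50 needs. Site density scales with the
# coarser raster so the per-area sampling-site density matches the
# 5-arcmin default.
survey_params <- function(...) {
  args <- utils::modifyList(
    list(
      cell_size_arcmin = 30, n_records = 80000, n_species = 10000,
      n_hotspots = 15, hotspot_sd_deg = 4, hotspot_weight = 0.25,
      records_per_sample = 1.5, sites_per_cell = 60, dates_per_site = 12,
      lat_width_meanlog = log(10), lon_width_min = 5, lon_width_max = 15,
      temp_texture_amp = 5
    ),
    list(...)
  )
  do.call(hexrich::generator_params, args)
}

# One default grid per test run (building it is ~0.5 s).
shared_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- hexrich::build_hex_grid()
    g
  }
})
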