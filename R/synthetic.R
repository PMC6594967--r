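#' Synthetic occurrence worlds
#'
#' The generator builds a study system with the statistical structure the
#' analysis assumes, together with its ground truth, so the whole pipeline
#' can be exercised and validated by parameter recovery: a bimodal
#' latitudinal richness profile (primary low-latitude peak, equatorial dip,
#' secondary high-latitude peak), exponential richness decay with depth, a
#' log-series species-abundance distribution, strong spatial effort hotspots,
#' and environmental layers correlated with latitude and depth. An
#' env-richness coupling coefficient blends the geometric profile (coupling
#' 0) with a monotone transform of the temperature field (coupling 1).
#'
#' @name synthetic_data
NULL

#' Generator parameters
#'
#' Constructor with validation for the synthetic-world parameter set; all
#' defaults are the package's canonical study conditions.
#'
#' @param n_species Species-pool size.
#' @param n_records Number of occurrence records to draw.
#' @param bbox Study box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param lat_peak_primary,lat_peak_primary_sd,lat_peak_primary_amp Primary
#'   (low-latitude) Gaussian richness bump: centre (deg N), width, amplitude.
#' @param lat_peak_secondary,lat_peak_secondary_sd,lat_peak_secondary_amp
#'   Secondary high-latitude bump.
#' @param eq_dip_sd,eq_dip_amp Equatorial Gaussian dip (centred at 0 N).
#' @param lat_baseline,lat_floor Additive baseline and positive floor of the
#'   latitude profile.
#' @param depth_onset Depth (m) below which richness starts decaying.
#' @param depth_efold E-folding scale (m) of the exponential depth decay.
#' @param shallow_fraction Fraction of records drawn at depth <= 500 m.
#' @param coupling Env-richness coupling coefficient in \[0, 1\].
#' @param logseries_x Log-series shape parameter (0 < x < 1).
#' @param n_hotspots,hotspot_sd_deg,hotspot_weight Number, width (deg) and
#'   total effort share of sampling-effort hotspots; `hotspot_centers` may
#'   fix their locations as a 2-column (lat, lon) matrix.
#' @param hotspot_centers Optional matrix of hotspot centres.
#' @param cell_size_arcmin Raster resolution in arcminutes (default 5).
#' @param land_strip,land_strip_lon_max Latitude strip `c(lo, hi)` treated
#'   as land for longitudes below `land_strip_lon_max` (emulates the
#'   near-closed 60-70 N band).
#' @param records_per_sample Mean records per sampling event.
#' @param sites_per_cell Distinct sampling sites per raster cell.
#' @param dates_per_site Distinct sampling dates per site.
#' @param lat_width_meanlog,lat_width_sdlog Log-normal latitudinal range
#'   width (deg).
#' @param lon_width_min,lon_width_max Uniform longitudinal range width (deg).
#' @param depth_halfwidth_meanlog,depth_halfwidth_sdlog Log-normal depth
#'   range half-width (m).
#' @param temp_texture_amp Amplitude (deg C) of the longitudinal temperature
#'   texture.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n_species = 2000,
                             n_records = 20000,
                             bbox = c(0, 90, 100, 180),
                             lat_peak_primary = 10,
                             lat_peak_primary_sd = 12,
                             lat_peak_primary_amp = 1,
                             lat_peak_secondary = 80,
                             lat_peak_secondary_sd = 8,
                             lat_peak_secondary_amp = 0.5,
                             eq_dip_sd = 4,
                             eq_dip_amp = 0.6,
                             lat_baseline = 0.15,
                             lat_floor = 0.05,
                             depth_onset = 100,
                             depth_efold = 800,
                             shallow_fraction = 0.83,
                             coupling = 0,
                             logseries_x = 0.95,
                             n_hotspots = 3,
                             hotspot_sd_deg = 3,
                             hotspot_weight = 0.5,
                             hotspot_centers = NULL,
                             cell_size_arcmin = 5,
                             land_strip = c(60, 70),
                             land_strip_lon_max = 165,
                             records_per_sample = 3,
                             sites_per_cell = 5,
                             dates_per_site = 3,
                             lat_width_meanlog = log(15),
                             lat_width_sdlog = 0.5,
                             lon_width_min = 10,
                             lon_width_max = 30,
                             depth_halfwidth_meanlog = log(150),
                             depth_halfwidth_sdlog = 0.7,
                             temp_texture_amp = 2,
                             seed = 1) {
  p <- as.list(environment())
  if (p$n_species < 0 || p$n_records < 0) {
    stop_hexrich("counts must be nonnegative", "parameter_error")
  }
  if (p$bbox[2] <= p$bbox[1] || p$bbox[4] <= p$bbox[3]) {
    stop_hexrich("invalid bounding box", "parameter_error")
  }
  if (p$depth_efold <= 0 || p$cell_size_arcmin <= 0) {
    stop_hexrich("scales must be positive", "parameter_error")
  }
  if (p$coupling < 0 || p$coupling > 1) {
    stop_hexrich("coupling coefficient must lie in [0, 1]", "parameter_error")
  }
  if (p$logseries_x <= 0 || p$logseries_x >= 1) {
    stop_hexrich("log-series shape must lie in (0, 1)", "parameter_error")
  }
  if (p$shallow_fraction <= 0 || p$shallow_fraction >= 1) {
    stop_hexrich("shallow_fraction must lie in (0, 1)", "parameter_error")
  }
  structure(p, class = "generator_params")
}

# Deterministic pseudo-random hash in [0, 1) used for fixed world features
# (site positions, site date pools) that must not consume the RNG stream.
det_hash <- function(a, b, k, seed = 0) {
  x <- sin(a * 12.9898 + b * 78.233 + k * 37.719 + seed * 0.5453) * 43758.5453
  x - floor(x)
}

# --- latitude and depth profiles -------------------------------------------

lat_profile <- function(lat, p) {
  g <- p$lat_baseline +
    p$lat_peak_primary_amp *
      exp(-(lat - p$lat_peak_primary)^2 / (2 * p$lat_peak_primary_sd^2)) +
    p$lat_peak_secondary_amp *
      exp(-(lat - p$lat_peak_secondary)^2 / (2 * p$lat_peak_secondary_sd^2)) -
    p$eq_dip_amp * exp(-lat^2 / (2 * p$eq_dip_sd^2))
  pmax(g, p$lat_floor)
}

depth_factor <- function(depth, p) {
  ifelse(depth <= p$depth_onset, 1, exp(-(depth - p$depth_onset) / p$depth_efold))
}

# Record-depth distribution: piecewise-uniform masses over the shallow
# intervals 0-50 / 50-100 / 100-200 / 200-500 m (relative weights mirroring
# observed shallow sampling), truncated-exponential tail below 500 m; total
# shallow mass = shallow_fraction.
shallow_breaks <- c(0, 50, 100, 200, 500)
shallow_masses <- c(0.520, 0.116, 0.114, 0.250)

depth_cdf <- function(z, p, depth_max = 10900) {
  sf <- p$shallow_fraction
  w <- shallow_masses / sum(shallow_masses)
  cw <- c(0, cumsum(w))
  shallow_val <- function(zz) {
    i <- pmax(1, pmin(4, findInterval(zz, shallow_breaks)))
    frac <- (zz - shallow_breaks[i]) / diff(shallow_breaks)[i]
    sf * (cw[i] + w[i] * frac)
  }
  deep_val <- function(zz) {
    lam <- 1 / p$depth_efold
    norm <- 1 - exp(-lam * (depth_max - 500))
    sf + (1 - sf) * (1 - exp(-lam * (zz - 500))) / norm
  }
  z <- pmin(pmax(z, 0), depth_max)
  ifelse(z <= 500, shallow_val(z), deep_val(z))
}

depth_icdf <- function(u, p, depth_max = 10900) {
  sf <- p$shallow_fraction
  w <- shallow_masses / sum(shallow_masses)
  cw <- c(0, cumsum(w))
  u <- pmin(pmax(u, 0), 1)
  shallow_inv <- function(uu) {
    us <- uu / sf
    i <- pmax(1, pmin(4, findInterval(us, cw)))
    shallow_breaks[i] + (us - cw[i]) / w[i] * diff(shallow_breaks)[i]
  }
  deep_inv <- function(uu) {
    lam <- 1 / p$depth_efold
    norm <- 1 - exp(-lam * (depth_max - 500))
    ud <- (uu - sf) / (1 - sf)
    500 - log(1 - ud * norm) / lam
  }
  ifelse(u <= sf, shallow_inv(u), deep_inv(u))
}

# --- log-series abundance distribution -------------------------------------

#' Sample from and fit the log-series abundance distribution
#'
#' `rlogseries()` draws abundances with P(n) proportional to x^n / n;
#' `fit_logseries()` recovers the shape by maximum likelihood (the MLE
#' solves mean(n) = -x / ((1 - x) log(1 - x))).
#'
#' @param n Number of draws.
#' @param x Shape parameter in (0, 1).
#' @return `rlogseries()`: integer vector; `fit_logseries()`: the fitted x.
#' @export
rlogseries <- function(n, x) {
  stopifnot(x > 0, x < 1)
  # Precompute the pmf until the tail is negligible.
  kmax <- min(ceiling(log(1e-12) / log(x)) + 10, 1e6)
  k <- seq_len(kmax)
  pmf <- x^k / k
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(runif(n), cdf) + 1L
}

#' @rdname rlogseries
#' @param counts Integer abundance vector to fit.
#' @export
fit_logseries <- function(counts) {
  mbar <- mean(counts)
  if (mbar <= 1) {
    return(1e-6)
  }
  f <- function(x) -x / ((1 - x) * log(1 - x)) - mbar
  uniroot(f, c(1e-8, 1 - 1e-12), tol = 1e-12)$root
}

# --- world construction -----------------------------------------------------

smooth_field <- function(lat_mat, lon_mat, n_bumps, scale_deg, bbox) {
  f <- matrix(0, nrow(lat_mat), ncol(lat_mat))
  for (b in seq_len(n_bumps)) {
    cl <- runif(1, bbox[1], bbox[2])
    cn <- runif(1, bbox[3], bbox[4])
    s <- runif(1, scale_deg / 2, scale_deg * 1.5)
    a <- rnorm(1)
    f <- f + a * exp(-((lat_mat - cl)^2 + (lon_mat - cn)^2) / (2 * s^2))
  }
  if (stats::sd(f) > 0) f <- (f - mean(f)) / stats::sd(f)
  f
}

#' Generate a synthetic world
#'
#' Builds the full study system: 8 environmental rasters, ocean mask, effort
#' surface, species pool with geographic/depth ranges and log-series
#' abundances, and the ground-truth richness surface. Deterministic given
#' `params$seed`.
#'
#' @param params A [generator_params()] list.
#' @return An object of class `synthetic_truth`: `params`, `species`
#'   (tibble of ranges), `env_rasters` (named list of [env_raster()]),
#'   `ocean_mask`, `effort` (weights raster summing to 1 over ocean),
#'   `richness_surface(lat, lon, depth)`, `temp_fun(lat, lon)` and
#'   `temperature_at(lat, lon, depth)` closures, and `seed`.
#' @export
generate_world <- function(params = generator_params()) {
  p <- params
  bbox <- p$bbox
  with_seed(p$seed, {
    cs <- p$cell_size_arcmin / 60
    nr <- round((bbox[2] - bbox[1]) / cs)
    nc <- round((bbox[4] - bbox[3]) / cs)
    lat_c <- bbox[1] + (seq_len(nr) - 0.5) * cs
    lon_c <- bbox[3] + (seq_len(nc) - 0.5) * cs
    lat_mat <- matrix(lat_c, nr, nc)
    lon_mat <- matrix(lon_c, nr, nc, byrow = TRUE)

    mk <- function(vals, name, units) {
      env_raster(vals, bbox[1], bbox[3], p$cell_size_arcmin, name, units)
    }

    # Ocean mask: all ocean except a mostly-land latitude strip.
    ocean <- matrix(1, nr, nc)
    ocean[lat_mat >= p$land_strip[1] & lat_mat < p$land_strip[2] &
      lon_mat < p$land_strip_lon_max] <- 0

    # Temperature: strictly decreasing in latitude, with a longitudinal
    # texture (constant in latitude, so monotonicity is preserved).
    ph1 <- runif(1, 0, 2 * pi)
    ph2 <- runif(1, 0, 2 * pi)
    dlon <- bbox[4] - bbox[3]
    temp_fun <- function(lat, lon) {
      tex <- 0.7 * sin(2 * pi * 3 * (lon - bbox[3]) / dlon + ph1) +
        0.3 * sin(2 * pi * 5 * (lon - bbox[3]) / dlon + ph2)
      29 - 27 * (pmax(lat, 0) / 90)^1.1 + p$temp_texture_amp * tex
    }
    temperature_at <- function(lat, lon, depth) {
      tsurf <- temp_fun(lat, lon)
      decay <- exp(-depth / 2500)
      tsurf * decay - 1.8 * (1 - decay)
    }

    temp_v <- temp_fun(lat_mat, lon_mat)
    # Mesoscale (6-degree) noise with amplitudes comparable to each
    # variable's latitudinal trend: predictors correlate with latitude but
    # none is an invertible proxy for it.
    noise <- function(scale_deg = 6) smooth_field(lat_mat, lon_mat, 12, scale_deg, bbox)
    env <- list(
      temperature = mk(temp_v, "temperature", "degC"),
      salinity = mk(34.5 - 2 * (lat_mat / 90) + 1.2 * noise(), "salinity", "PSS"),
      dissolved_oxygen = mk(
        0.20 + 0.15 * (lat_mat / 90) + 0.09 * noise(),
        "dissolved_oxygen", "mol.m-3"
      ),
      saturated_oxygen = mk(
        85 + 10 * (lat_mat / 90) + 6 * noise(),
        "saturated_oxygen", "percent"
      ),
      productivity = mk(
        0.002 + 0.004 * exp(-((lat_mat - 45) / 25)^2) + 0.0025 * noise(),
        "productivity", "g.m-3.d-1"
      ),
      chlorophyll = mk(
        pmax(0.1 + 0.6 * exp(-((lat_mat - 50) / 20)^2) + 0.35 * noise(), 0.02),
        "chlorophyll", "mg.m-3"
      ),
      current_velocity = mk(
        pmax(0.05 + 0.15 * abs(sin(deg2rad(2 * lat_mat))) + 0.09 * noise(), 0.01),
        "current_velocity", "m.s-1"
      ),
      nitrate = mk(
        pmax(0.002 + 0.025 * (lat_mat / 90) + 0.015 * noise(), 0.0005),
        "nitrate", "mol.m-3"
      )
    )

    # Richness surface: blend of the geometric latitude profile and a
    # monotone transform of temperature, both normalised to unit mean over
    # ocean, times the exponential depth factor.
    ocean_idx <- which(ocean == 1)
    g_vals <- lat_profile(lat_mat, p)
    h_vals <- exp(0.08 * temp_v)
    g_norm <- mean(g_vals[ocean_idx])
    h_norm <- mean(h_vals[ocean_idx])
    cpl <- p$coupling
    richness_ll_fun <- function(lat, lon) {
      (1 - cpl) * lat_profile(lat, p) / g_norm +
        cpl * exp(0.08 * temp_fun(lat, lon)) / h_norm
    }
    richness_surface <- function(lat, lon, depth = 0) {
      richness_ll_fun(lat, lon) * depth_factor(depth, p)
    }
    rich_ll <- (1 - cpl) * g_vals / g_norm + cpl * h_vals / h_norm

    # Effort surface: uniform background + Gaussian hotspots placed
    # preferentially in species-rich ocean cells.
    if (is.null(p$hotspot_centers) && p$n_hotspots > 0) {
      hs_idx <- sample(ocean_idx, p$n_hotspots, prob = rich_ll[ocean_idx]^2)
      hs <- cbind(lat_mat[hs_idx], lon_mat[hs_idx])
    } else {
      hs <- p$hotspot_centers
    }
    # Background effort is uniform per unit AREA: on a lat-lon grid that
    # means cos(latitude) weights per cell.
    eff <- cos(deg2rad(lat_mat))
    eff_hot <- matrix(0, nr, nc)
    if (!is.null(hs) && nrow(hs) > 0) {
      for (i in seq_len(nrow(hs))) {
        eff_hot <- eff_hot + exp(
          -((lat_mat - hs[i, 1])^2 + (lon_mat - hs[i, 2])^2) /
            (2 * p$hotspot_sd_deg^2)
        )
      }
    }
    eff[ocean == 0] <- 0
    eff_hot[ocean == 0] <- 0
    w_unif <- if (sum(eff) > 0) eff / sum(eff) else eff
    w_hot <- if (sum(eff_hot) > 0) eff_hot / sum(eff_hot) else w_unif
    hw <- if (is.null(hs) || nrow(hs) == 0) 0 else p$hotspot_weight
    effort <- (1 - hw) * w_unif + hw * w_hot

    # Species pool.
    species <- if (p$n_species > 0) {
      # Centre density follows the richness surface per unit AREA
      # (cos(lat) converts degree-cell density to physical density).
      centre_idx <- sample(ocean_idx, p$n_species,
        replace = TRUE,
        prob = (rich_ll * cos(deg2rad(lat_mat)))[ocean_idx]
      )
      lat_ctr <- lat_mat[centre_idx] + runif(p$n_species, -cs / 2, cs / 2)
      lon_ctr <- lon_mat[centre_idx] + runif(p$n_species, -cs / 2, cs / 2)
      lat_w <- rlnorm(p$n_species, p$lat_width_meanlog, p$lat_width_sdlog)
      # Longitudinal widths are physical: drawn as equatorial degrees and
      # widened by 1/cos(latitude) so a range spans the same east-west
      # distance at any latitude (high-latitude ranges tend circumpolar).
      lon_w <- runif(p$n_species, p$lon_width_min, p$lon_width_max) /
        pmax(cos(deg2rad(pmin(abs(lat_ctr), 89))), 0.05)
      lat_min <- pmax(bbox[1], lat_ctr - lat_w / 2)
      lat_max <- pmin(bbox[2], lat_ctr + lat_w / 2)
      lon_min <- pmax(bbox[3], lon_ctr - lon_w / 2)
      lon_max <- pmin(bbox[4], lon_ctr + lon_w / 2)

      shallow_sp <- runif(p$n_species) < p$shallow_fraction
      u_dep <- ifelse(
        shallow_sp,
        runif(p$n_species, 0, depth_cdf(500, p)),
        runif(p$n_species, depth_cdf(500, p), 1)
      )
      dep_ctr <- depth_icdf(u_dep, p)
      dep_hw <- rlnorm(p$n_species, p$depth_halfwidth_meanlog, p$depth_halfwidth_sdlog)
      depth_min <- pmax(0, dep_ctr - dep_hw)
      depth_max <- pmin(10900, dep_ctr + dep_hw)

      tibble::tibble(
        species_id = sprintf("sp%05d", seq_len(p$n_species)),
        lat_center = (lat_min + lat_max) / 2,
        lat_width = lat_max - lat_min,
        lon_center = (lon_min + lon_max) / 2,
        lon_width = lon_max - lon_min,
        lat_min = lat_min, lat_max = lat_max,
        lon_min = lon_min, lon_max = lon_max,
        depth_min = depth_min, depth_max = depth_max,
        abundance = as.numeric(rlogseries(p$n_species, p$logseries_x)),
        habitat = sample(
          c("benthic", "pelagic"), p$n_species,
          replace = TRUE, prob = c(0.65, 0.35)
        )
      )
    } else {
      tibble::tibble(
        species_id = character(0), lat_center = numeric(0),
        lat_width = numeric(0), lon_center = numeric(0),
        lon_width = numeric(0), lat_min = numeric(0), lat_max = numeric(0),
        lon_min = numeric(0), lon_max = numeric(0), depth_min = numeric(0),
        depth_max = numeric(0), abundance = numeric(0), habitat = character(0)
      )
    }

    structure(
      list(
        params = p,
        species = species,
        env_rasters = env,
        ocean_mask = mk(ocean, "ocean_mask", "binary"),
        effort = mk(effort, "effort", "weight"),
        richness_surface = richness_surface,
        temp_fun = temp_fun,
        temperature_at = temperature_at,
        seed = p$seed
      ),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d species, %d x %d raster cells, coupling %.2f, seed %d\n",
    nrow(x$species), nrow(x$ocean_mask$values), ncol(x$ocean_mask$values),
    x$params$coupling, x$seed
  ))
  invisible(x)
}

#' Sample occurrence records from a synthetic world
#'
#' Sampling events (site x date) are drawn in proportion to the effort
#' surface; each event yields on average `records_per_sample` records. Per
#' record a depth stratum is chosen (shallow with probability
#' `shallow_fraction`), a species is drawn with probability proportional to
#' abundance among pool members whose range covers the site and reaches the
#' stratum, and a depth is drawn from the world's depth profile restricted
#' to the species' range within the stratum — so every record lies inside
#' its species' range. Site positions and per-site date pools are fixed
#' features of the world, making the number of distinct (date, location)
#' samples per cell scale with effort.
#'
#' @param truth A [generate_world()] result.
#' @param n_records Number of records to draw (default: from the params).
#' @param seed Integer seed for the sampling stream.
#' @return A Darwin-Core-style tibble with `occurrenceID`, `scientificName`,
#'   `decimalLatitude`, `decimalLongitude`, `depth`, `eventDate`,
#'   `datasetID`; exactly `n_records` rows.
#' @export
sample_occurrences <- function(truth, n_records = truth$params$n_records,
                               seed = 1) {
  p <- truth$params
  if (n_records < 0) stop_hexrich("n_records must be >= 0", "parameter_error")
  dwc_empty <- tibble::tibble(
    occurrenceID = character(0), scientificName = character(0),
    decimalLatitude = numeric(0), decimalLongitude = numeric(0),
    depth = numeric(0), eventDate = as.Date(character(0)),
    datasetID = character(0)
  )
  if (n_records == 0) {
    return(dwc_empty)
  }
  eff <- truth$effort$values
  if (sum(eff) <= 0) {
    stop_hexrich("effort surface is all zero", "generation_error")
  }
  if (nrow(truth$species) == 0) {
    stop_hexrich("species pool is empty", "generation_error")
  }
  cs <- raster_cell_deg(truth$effort)
  nr <- nrow(eff)
  ocean_idx <- which(eff > 0)
  w <- eff[ocean_idx]

  sp <- truth$species
  with_seed(seed, {
    # Draw events until their record counts cover n_records, then truncate.
    mean_rpe <- max(1, p$records_per_sample)
    counts <- integer(0)
    while (sum(counts) < n_records) {
      batch <- ceiling((n_records - sum(counts)) / mean_rpe * 1.3) + 10
      counts <- c(counts, 1L + rpois(batch, mean_rpe - 1))
    }
    n_events <- which(cumsum(counts) >= n_records)[1]
    counts <- counts[seq_len(n_events)]
    counts[n_events] <- n_records - sum(counts[-n_events])

    ev_cell <- sample(ocean_idx, n_events, replace = TRUE, prob = w)
    ev_site <- sample.int(p$sites_per_cell, n_events, replace = TRUE)
    ev_date_k <- sample.int(p$dates_per_site, n_events, replace = TRUE)

    # Deterministic world features: site coordinates and date pools.
    ci <- (ev_cell - 1) %% nr + 1
    cj <- (ev_cell - 1) %/% nr + 1
    site_lat <- truth$effort$origin_lat +
      (ci - 1 + det_hash(ev_cell, ev_site, 1, p$seed)) * cs
    site_lon <- truth$effort$origin_lon +
      (cj - 1 + det_hash(ev_cell, ev_site, 2, p$seed)) * cs
    ev_date <- as.Date("2000-01-01") +
      floor(det_hash(ev_cell, ev_site, 100 + ev_date_k, p$seed) * 7305)

    rec_ev <- rep.int(seq_len(n_events), counts)
    n <- n_records
    rec_shallow <- runif(n) < p$shallow_fraction

    # Species choice per record, grouped by site for vectorised range tests.
    site_key <- paste(ev_cell, ev_site)
    rec_sp <- integer(n)
    ev_by_site <- split(seq_len(n_events), site_key)
    recs_by_site <- split(seq_len(n), site_key[rec_ev])
    # Plain-vector views of the pool for the hot loops.
    sp_lat_min <- sp$lat_min
    sp_lat_max <- sp$lat_max
    sp_lon_min <- sp$lon_min
    sp_lon_max <- sp$lon_max
    sp_shallow_ok <- sp$depth_min <= 500
    sp_deep_ok <- sp$depth_max > 500
    sp_abund <- sp$abundance
    n_sp <- nrow(sp)
    # Species assignment in two phases. Phase 1 is vectorised rejection
    # sampling: per coarse block, candidates are drawn abundance-weighted
    # from the species whose (half-block-expanded) range intersects the
    # block, and accepted iff the range covers the record's exact site and
    # reaches its stratum — which is exactly an abundance-weighted draw
    # among the site-covering, stratum-reaching species. Phase 2 resolves
    # the few stragglers (sites with empty or tiny candidate sets) with the
    # exact per-site search, including the stratum-flip fallback.
    block_deg <- 5
    superset <- new.env(parent = emptyenv())
    block_superset <- function(key, blat, blon) {
      got <- superset[[key]]
      if (!is.null(got)) {
        return(got)
      }
      half <- block_deg / 2
      idx <- which(
        sp_lat_min - half <= blat & blat <= sp_lat_max + half &
          sp_lon_min - half <= blon & blon <= sp_lon_max + half
      )
      superset[[key]] <- idx
      idx
    }
    rec_lat <- site_lat[rec_ev]
    rec_lon <- site_lon[rec_ev]
    rec_block <- paste(
      floor(rec_lat / block_deg), floor(rec_lon / block_deg)
    )
    assigned <- logical(n)
    for (round in seq_len(30)) {
      todo <- which(!assigned)
      if (!length(todo)) break
      by_block <- split(todo, rec_block[todo])
      draw_at <- integer(n)
      for (b in names(by_block)) {
        ii <- by_block[[b]]
        blat <- (floor(rec_lat[ii[1]] / block_deg) + 0.5) * block_deg
        blon <- (floor(rec_lon[ii[1]] / block_deg) + 0.5) * block_deg
        pool <- block_superset(b, blat, blon)
        if (length(pool) < 2) next # straggler path handles these blocks
        draw_at[ii] <- pool[sample.int(
          length(pool), length(ii),
          replace = TRUE, prob = sp_abund[pool]
        )]
      }
      d <- draw_at[todo]
      ok <- d > 0 &
        sp_lat_min[d] <= rec_lat[todo] & rec_lat[todo] <= sp_lat_max[d] &
        sp_lon_min[d] <= rec_lon[todo] & rec_lon[todo] <= sp_lon_max[d] &
        ifelse(rec_shallow[todo], sp_shallow_ok[d], sp_deep_ok[d])
      ok[is.na(ok)] <- FALSE
      hit <- todo[ok]
      rec_sp[hit] <- d[ok]
      assigned[hit] <- TRUE
    }
    # Phase 2: exact search for whatever remains.
    left <- which(!assigned)
    if (length(left)) {
      for (sk in unique(site_key[rec_ev[left]])) {
        recs <- left[site_key[rec_ev[left]] == sk]
        slat <- rec_lat[recs[1]]
        slon <- rec_lon[recs[1]]
        cover <- which(
          sp_lat_min <= slat & slat <= sp_lat_max &
            sp_lon_min <= slon & slon <= sp_lon_max
        )
        if (!length(cover)) {
          cover <- which(sp_lat_min <= slat & slat <= sp_lat_max)
        }
        if (!length(cover)) cover <- seq_len(n_sp)
        cand_sh <- cover[sp_shallow_ok[cover]]
        cand_dp <- cover[sp_deep_ok[cover]]
        for (stratum_shallow in c(TRUE, FALSE)) {
          rr <- recs[rec_shallow[recs] == stratum_shallow]
          if (!length(rr)) next
          cand <- if (stratum_shallow) cand_sh else cand_dp
          if (!length(cand)) {
            # No pool member reaches this stratum here: flip the stratum.
            cand <- if (stratum_shallow) cand_dp else cand_sh
            rec_shallow[rr] <- !stratum_shallow
          }
          if (!length(cand)) cand <- cover
          rec_sp[rr] <- cand[sample.int(
            length(cand), length(rr),
            replace = TRUE,
            prob = sp_abund[cand]
          )]
        }
      }
    }

    # Depth: world depth profile restricted to species range within stratum.
    lo <- ifelse(rec_shallow, pmax(0, sp$depth_min[rec_sp]),
      pmax(500, sp$depth_min[rec_sp])
    )
    hi <- ifelse(rec_shallow, pmin(500, sp$depth_max[rec_sp]),
      sp$depth_max[rec_sp]
    )
    degenerate <- hi <= lo
    lo[degenerate] <- sp$depth_min[rec_sp][degenerate]
    hi[degenerate] <- sp$depth_max[rec_sp][degenerate]
    u <- runif(n)
    flo <- depth_cdf(lo, p)
    fhi <- depth_cdf(hi, p)
    depth <- depth_icdf(flo + u * pmax(fhi - flo, 1e-12), p)
    depth <- pmin(pmax(depth, lo), hi)

    tibble::tibble(
      occurrenceID = sprintf("rec%07d", seq_len(n)),
      scientificName = sp$species_id[rec_sp],
      decimalLatitude = site_lat[rec_ev],
      decimalLongitude = site_lon[rec_ev],
      depth = depth,
      eventDate = ev_date[rec_ev],
      datasetID = "synthetic-survey"
    )
  })
}

#' Write a synthetic world to disk
#'
#' Environmental rasters, ocean mask and effort surface go out as headered
#' gridded text ([write_env_raster()]); the species pool as CSV; the
#' parameter set and summary statistics as JSON.
#'
#' @param truth A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(truth$env_rasters)) {
    write_env_raster(
      truth$env_rasters[[nm]],
      file.path(dir, paste0("env_", nm, ".txt"))
    )
  }
  write_env_raster(truth$ocean_mask, file.path(dir, "ocean_mask.txt"))
  write_env_raster(truth$effort, file.path(dir, "effort.txt"))
  readr::write_csv(truth$species, file.path(dir, "species_pool.csv"))
  params <- truth$params
  params$hotspot_centers <- NULL
  jsonlite::write_json(
    list(
      params = unclass(params),
      n_species = nrow(truth$species),
      seed = truth$seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
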