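#' Sampling events from occurrence records
#'
#' A sample (sampling event) is a unique combination of event date and
#' location, location being latitude/longitude rounded to `rounding` decimal
#' places (4 dp is roughly 11 m). Records without a date cannot be placed in
#' a sample and are excluded (their count is attached as the
#' `n_dateless` attribute).
#'
#' @param records Occurrence tibble with `species`, `latitude`, `longitude`,
#'   `event_date` columns (see [as_occurrences()]); a `cell_id` column is
#'   carried through when present.
#' @param rounding Decimal places used for the location part of the sample key.
#' @return A tibble with one row per sample: `sample_id`, `event_date`,
#'   `lat`, `lon`, optional `cell_id`, the distinct `species` list-column,
#'   `n_species` and `n_records`.
#' @export
build_samples <- function(records, rounding = 4) {
  records <- tibble::as_tibble(records)
  n_dateless <- sum(is.na(records$event_date))
  dated <- dplyr::filter(records, !is.na(.data$event_date))
  has_cell <- "cell_id" %in% names(dated)
  dated <- dated |>
    dplyr::mutate(
      lat = round(.data$latitude, rounding),
      lon = round(.data$longitude, rounding),
      sample_id = paste(.data$event_date, .data$lat, .data$lon, sep = "|")
    )
  out <- dated |>
    dplyr::group_by(.data$sample_id, .data$event_date, .data$lat, .data$lon) |>
    dplyr::summarise(
      cell_id = if (has_cell) dplyr::first(.data$cell_id) else NA_character_,
      n_species = length(unique(.data$species)),
      n_records = dplyr::n(),
      # assigned last: earlier summaries must see the input column
      species = list(sort(unique(.data$species))),
      .groups = "drop"
    ) |>
    dplyr::relocate("species", .after = "cell_id")
  if (!has_cell) out$cell_id <- NULL
  attr(out, "n_dateless") <- n_dateless
  out
}

#' Incidence summary of a set of records
#'
#' Collects the quantities sample-based rarefaction needs: the number of
#' samples `N`, observed species `S_obs`, per-species incidences `n_i`
#' (samples containing species i), per-species record counts `r_i` and total
#' records `R`. The sample-by-species membership is retained for
#' bootstrapping.
#'
#' @inheritParams build_samples
#' @return An object of class `incidence_summary`.
#' @export
incidence_summary <- function(records, rounding = 4) {
  records <- tibble::as_tibble(records)
  dated <- dplyr::filter(records, !is.na(.data$event_date))
  if (nrow(dated) == 0) {
    return(structure(
      list(
        N = 0L, S_obs = 0L, R = 0L,
        n_i = integer(0), r_i = integer(0),
        membership = tibble::tibble(
          sample = integer(0), species = character(0), n_rec = integer(0)
        )
      ),
      class = "incidence_summary"
    ))
  }
  dated <- dplyr::mutate(
    dated,
    sample_id = paste(
      .data$event_date,
      round(.data$latitude, rounding),
      round(.data$longitude, rounding),
      sep = "|"
    )
  )
  membership <- dplyr::count(dated, .data$sample_id, .data$species, name = "n_rec")
  sample_ids <- sort(unique(membership$sample_id))
  membership$sample <- match(membership$sample_id, sample_ids)
  membership$sample_id <- NULL
  n_i <- table(membership$species)
  r_i <- tapply(membership$n_rec, membership$species, sum)
  sp <- sort(unique(membership$species))
  structure(
    list(
      N = length(sample_ids),
      S_obs = length(sp),
      R = nrow(dated),
      n_i = as.integer(n_i[sp]) |> setNames(sp),
      r_i = as.integer(r_i[sp]) |> setNames(sp),
      membership = membership
    ),
    class = "incidence_summary"
  )
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf(
    "<incidence_summary> N = %d samples, S_obs = %d species, R = %d records\n",
    x$N, x$S_obs, x$R
  ))
  invisible(x)
}

# Closed-form rarefaction expectation from incidence (or record) frequencies:
# E[S_m] = S - sum_i C(T - t_i, m) / C(T, m), evaluated in log-gamma space.
rarefy_expect <- function(t_i, total, m) {
  if (m > total) {
    return(NA_real_)
  }
  log_ratio <- lchoose(total - t_i, m) - lchoose(total, m)
  sum(1 - exp(pmin(log_ratio, 0)))
}

#' Rarefied expected species richness
#'
#' Expected number of species found in `m` randomly drawn sampling units,
#' computed from the closed-form hypergeometric expectation
#' `E[S_m] = S_obs - sum_i C(N - n_i, m) / C(N, m)`. With `mode = "samples"`
#' the unit is a sampling event (date x location); with `mode = "records"`
#' the unit is an individual occurrence record and record counts replace
#' incidences. `m = 50` gives the ES50 statistic.
#'
#' @param inc An [incidence_summary()].
#' @param m Number of sampling units to rarefy to (default 50).
#' @param mode `"samples"` (default) or `"records"`.
#' @return The expectation, or `NA` when `m` exceeds the available units.
#' @export
rarefied_richness <- function(inc, m = 50, mode = c("samples", "records")) {
  mode <- match.arg(mode)
  if (length(m) != 1 || is.na(m) || m <= 0 || m != round(m)) {
    stop_hexrich("`m` must be a positive integer", "domain_error")
  }
  if (mode == "samples") {
    rarefy_expect(inc$n_i, inc$N, m)
  } else {
    rarefy_expect(inc$r_i, inc$R, m)
  }
}

#' Bootstrap standard error of rarefied richness
#'
#' Resamples sampling units (samples or records, matching `mode`) with
#' replacement `B` times, recomputes the rarefaction expectation on each
#' resample, and reports the standard deviation. Deterministic given `seed`.
#'
#' @inheritParams rarefied_richness
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return Bootstrap standard error (`NA` when the statistic is undefined).
#' @export
rarefied_se <- function(inc, m = 50, B = 200, seed = 1,
                        mode = c("samples", "records")) {
  mode <- match.arg(mode)
  if (B < 2) stop_hexrich("`B` must be at least 2", "domain_error")
  if (mode == "samples" && m > inc$N) {
    return(NA_real_)
  }
  if (mode == "records" && m > inc$R) {
    return(NA_real_)
  }
  with_seed(seed, {
    if (mode == "samples") {
      sp_samples <- split(inc$membership$sample, inc$membership$species)
      reps <- vapply(seq_len(B), function(b) {
        cnt <- tabulate(
          sample.int(inc$N, inc$N, replace = TRUE),
          nbins = inc$N
        )
        n_new <- vapply(sp_samples, function(ix) sum(cnt[ix]), numeric(1))
        rarefy_expect(n_new, inc$N, m)
      }, numeric(1))
    } else {
      p <- inc$r_i / inc$R
      reps <- vapply(seq_len(B), function(b) {
        r_new <- as.vector(stats::rmultinom(1, inc$R, p))
        rarefy_expect(r_new, inc$R, m)
      }, numeric(1))
    }
    stats::sd(reps)
  })
}

# Vectorised per-group rarefaction: for each combination of `by` columns,
# the number of sampling units and the closed-form E[S_m] (NA when the group
# holds fewer than m units). Only dated records participate.
cell_rarefaction <- function(records, m, mode, rounding, by = "cell_id") {
  dated <- dplyr::filter(records, !is.na(.data$event_date))
  if (nrow(dated) == 0) {
    out <- dplyr::distinct(records, dplyr::across(dplyr::all_of(by)))
    out$n_samples <- 0L
    out$es <- NA_real_
    return(out)
  }
  dated <- dplyr::mutate(
    dated,
    .sample = paste(
      .data$event_date,
      round(.data$latitude, rounding),
      round(.data$longitude, rounding),
      sep = "|"
    )
  )
  totals <- dated |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_samples = length(unique(.data$.sample)),
      .n_rec = dplyr::n(), .groups = "drop"
    )
  if (mode == "samples") {
    freq <- dated |>
      dplyr::distinct(
        dplyr::across(dplyr::all_of(by)), .data$species, .data$.sample
      ) |>
      dplyr::count(
        dplyr::across(dplyr::all_of(by)), .data$species,
        name = ".t"
      )
    totals$.total <- totals$n_samples
  } else {
    freq <- dated |>
      dplyr::count(dplyr::across(dplyr::all_of(by)), .data$species, name = ".t")
    totals$.total <- totals$.n_rec
  }
  es_tbl <- freq |>
    dplyr::left_join(totals, by = by) |>
    dplyr::mutate(
      .term = 1 - exp(pmin(lchoose(.data$.total - .data$.t, m) -
        lchoose(.data$.total, m), 0))
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      es = ifelse(.data$.total[1] >= m, sum(.data$.term), NA_real_),
      .groups = "drop"
    )
  dplyr::left_join(
    dplyr::select(totals, dplyr::all_of(by), "n_samples"),
    es_tbl,
    by = by
  )
}

stratum_of <- function(depth, depth_threshold) {
  dplyr::case_when(
    is.na(depth) ~ NA_character_,
    depth <= depth_threshold ~ "shallow",
    TRUE ~ "deep"
  )
}

subset_stratum <- function(records, stratum, depth_threshold) {
  if (stratum == "all") {
    return(records)
  }
  dplyr::filter(
    records,
    !is.na(.data$depth),
    stratum_of(.data$depth, depth_threshold) == stratum
  )
}

#' Per-hexagon diversity
#'
#' For every hexagonal cell (and depth stratum) computes sampling effort
#' (records and distinct samples), alpha diversity (observed species count)
#' and the rarefied ES `m` statistic with optional bootstrap standard error.
#' ES is reported as missing when a cell holds fewer than `m` sampling
#' units, keeping the statistic comparable across cells.
#'
#' @param records Occurrence tibble carrying `cell_id` (see
#'   [assign_to_cell()]).
#' @param grid Optional [build_hex_grid()] result; when supplied, cells with
#'   no records are included with zero effort (and centroid coordinates are
#'   attached).
#' @param m Rarefaction size (default 50).
#' @param mode Rarefaction unit, `"samples"` (default) or `"records"`.
#' @param strata Depth strata to report: any of `"all"`, `"shallow"`,
#'   `"deep"`.
#' @param depth_threshold Shallow/deep boundary in metres (default 500;
#'   shallow means depth <= threshold).
#' @param rounding Sample-location rounding, decimal places.
#' @param compute_se Whether to bootstrap the ES standard error.
#' @param B,seed Bootstrap replicates and seed (see [rarefied_se()]).
#' @return A tibble, one row per cell x stratum: `cell_id`, `stratum`,
#'   `n_records`, `n_samples`, `alpha`, `es`, `es_se`.
#' @export
cell_diversity <- function(records, grid = NULL, m = 50,
                           mode = c("samples", "records"),
                           strata = c("all", "shallow", "deep"),
                           depth_threshold = 500, rounding = 4,
                           compute_se = FALSE, B = 200, seed = 1) {
  mode <- match.arg(mode)
  strata <- match.arg(strata, several.ok = TRUE)
  records <- tibble::as_tibble(records)
  stopifnot("cell_id" %in% names(records))

  one_stratum <- function(st) {
    sub <- subset_stratum(records, st, depth_threshold)
    if (nrow(sub) == 0) {
      return(tibble::tibble(
        cell_id = character(0), stratum = character(0),
        n_records = integer(0), n_samples = integer(0),
        alpha = integer(0), es = numeric(0), es_se = numeric(0)
      ))
    }
    base <- sub |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(
        n_records = dplyr::n(),
        alpha = length(unique(.data$species)),
        .groups = "drop"
      )
    es_tbl <- cell_rarefaction(sub, m = m, mode = mode, rounding = rounding)
    out <- dplyr::left_join(base, es_tbl, by = "cell_id") |>
      tidyr::replace_na(list(n_samples = 0L))
    out$es_se <- NA_real_
    if (compute_se) {
      for (cid in out$cell_id[!is.na(out$es)]) {
        inc <- incidence_summary(
          sub[sub$cell_id == cid, ],
          rounding = rounding
        )
        out$es_se[out$cell_id == cid] <-
          rarefied_se(inc, m = m, B = B, seed = seed, mode = mode)
      }
    }
    dplyr::mutate(out, stratum = st, .after = "cell_id")
  }

  out <- purrr::map(strata, one_stratum) |> purrr::list_rbind()
  if (!is.null(grid)) {
    empty <- tidyr::expand_grid(
      cell_id = grid$cells$cell_id, stratum = strata
    )
    out <- dplyr::full_join(out, empty, by = c("cell_id", "stratum")) |>
      tidyr::replace_na(list(n_records = 0L, n_samples = 0L, alpha = 0L)) |>
      dplyr::left_join(
        dplyr::select(
          grid$cells, "cell_id", "centroid_lat", "centroid_lon"
        ),
        by = "cell_id"
      )
  }
  dplyr::arrange(out, .data$stratum, .data$cell_id)
}

#' Per-band diversity
#'
#' Aggregates records and per-cell diversity into latitudinal bands: gamma
#' diversity (distinct species per band), total records, the mean ES
#' statistic over cells with a defined value (cells are banded by centroid
#' latitude) with its standard error `SD / sqrt(n_cells)`, and the band's
#' ocean area when a mask is supplied.
#'
#' @param records Occurrence tibble (cleaned, with `species`, `latitude`).
#' @param cells A [cell_diversity()] table carrying `centroid_lat` (i.e.
#'   built with `grid =`).
#' @param band_width Band width in degrees (default 5).
#' @param ocean_mask Optional [env_raster()] mask for [band_ocean_area()].
#' @param bbox Study box, used for banding extent and ocean areas.
#' @param depth_threshold Shallow/deep boundary passed through to strata.
#' @return A tibble, one row per band x stratum, with `band`, `lat_lo`,
#'   `lat_mid`, `stratum`, `gamma`, `n_records`, `n_cells_es`, `mean_es`,
#'   `se_es`, `ocean_area_km2`.
#' @export
band_diversity <- function(records, cells, band_width = 5,
                           ocean_mask = NULL, bbox = c(0, 90, 100, 180),
                           depth_threshold = 500) {
  records <- tibble::as_tibble(records)
  n_band <- ceiling((bbox[2] - bbox[1]) / band_width)
  strata <- unique(cells$stratum)

  band_tbl <- tidyr::expand_grid(
    band = seq_len(n_band), stratum = strata
  ) |>
    dplyr::mutate(
      lat_lo = (.data$band - 1) * band_width,
      lat_mid = .data$lat_lo + band_width / 2
    )

  rec_part <- purrr::map(strata, function(st) {
    sub <- subset_stratum(records, st, depth_threshold)
    if (nrow(sub) == 0) {
      return(tibble::tibble(
        band = integer(0), stratum = character(0),
        gamma = integer(0), n_records = integer(0)
      ))
    }
    sub |>
      dplyr::mutate(band = assign_band(.data$latitude, band_width, bbox[2])) |>
      dplyr::group_by(.data$band) |>
      dplyr::summarise(
        gamma = length(unique(.data$species)),
        n_records = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::mutate(stratum = st)
  }) |> purrr::list_rbind()

  cell_part <- cells |>
    dplyr::filter(!is.na(.data$es), !is.na(.data$centroid_lat)) |>
    dplyr::filter(
      .data$centroid_lat >= bbox[1], .data$centroid_lat <= bbox[2]
    ) |>
    dplyr::mutate(
      band = assign_band(
        pmin(pmax(.data$centroid_lat, bbox[1]), bbox[2]), band_width, bbox[2]
      )
    ) |>
    dplyr::group_by(.data$band, .data$stratum) |>
    dplyr::summarise(
      n_cells_es = dplyr::n(),
      mean_es = mean(.data$es),
      se_es = stats::sd(.data$es) / sqrt(dplyr::n()),
      .groups = "drop"
    )

  out <- band_tbl |>
    dplyr::left_join(rec_part, by = c("band", "stratum")) |>
    dplyr::left_join(cell_part, by = c("band", "stratum")) |>
    tidyr::replace_na(list(gamma = 0L, n_records = 0L, n_cells_es = 0L))

  if (!is.null(ocean_mask)) {
    areas <- vapply(
      seq_len(n_band), band_ocean_area, numeric(1),
      ocean_mask = ocean_mask, bbox = bbox, band_width = band_width
    )
    out$ocean_area_km2 <- areas[out$band]
  } else {
    out$ocean_area_km2 <- NA_real_
  }
  dplyr::arrange(out, .data$stratum, .data$band)
}

#' Bathymetric diversity profile
#'
#' Per 100-m depth interval: total records, gamma diversity (distinct
#' species), mean per-hexagon alpha, and mean per-hexagon ES over
#' cell x interval groups holding at least `m` sampling units.
#'
#' @param records Occurrence tibble with `cell_id` and `depth` (records
#'   without depth are excluded and counted in the `n_no_depth` attribute).
#' @param interval Interval width in metres (default 100).
#' @param depth_max Bottom of the profiled domain (default 11,000 m).
#' @inheritParams cell_diversity
#' @return A tibble, one row per occupied interval: `interval`, `depth_lo`,
#'   `depth_mid`, `n_records`, `gamma`, `mean_alpha`, `n_cells_es`,
#'   `mean_es`, `se_es`.
#' @export
depth_profile <- function(records, interval = 100, depth_max = 11000,
                          m = 50, mode = c("samples", "records"),
                          rounding = 4) {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)
  stopifnot("cell_id" %in% names(records))
  n_no_depth <- sum(is.na(records$depth))
  rec <- records |>
    dplyr::filter(!is.na(.data$depth)) |>
    dplyr::mutate(
      interval = assign_depth_interval(.data$depth, interval, depth_max)
    )

  per_cell <- rec |>
    dplyr::group_by(.data$interval, .data$cell_id) |>
    dplyr::summarise(
      alpha = length(unique(.data$species)), .groups = "drop"
    ) |>
    dplyr::left_join(
      cell_rarefaction(
        rec,
        m = m, mode = mode, rounding = rounding,
        by = c("interval", "cell_id")
      ),
      by = c("interval", "cell_id")
    )

  out <- rec |>
    dplyr::group_by(.data$interval) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      gamma = length(unique(.data$species)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      per_cell |>
        dplyr::group_by(.data$interval) |>
        dplyr::summarise(
          mean_alpha = mean(.data$alpha),
          n_cells_es = sum(!is.na(.data$es)),
          mean_es = ifelse(
            any(!is.na(.data$es)), mean(.data$es, na.rm = TRUE), NA_real_
          ),
          se_es = ifelse(
            sum(!is.na(.data$es)) > 1,
            stats::sd(.data$es, na.rm = TRUE) / sqrt(sum(!is.na(.data$es))),
            NA_real_
          ),
          .groups = "drop"
        ),
      by = "interval"
    ) |>
    dplyr::mutate(
      depth_lo = (.data$interval - 1) * interval,
      depth_mid = .data$depth_lo + interval / 2,
      .after = "interval"
    ) |>
    dplyr::arrange(.data$interval)
  attr(out, "n_no_depth") <- n_no_depth
  out
}
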