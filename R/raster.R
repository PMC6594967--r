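#' Gridded environmental layer
#'
#' A minimal regular latitude-longitude raster used for environmental
#' predictors, sampling-effort surfaces and the ocean mask. Values are stored
#' in a matrix whose rows run south to north and whose columns run west to
#' east; cell centres sit half a cell in from the origin (the grid's
#' south-west corner).
#'
#' @param values Numeric matrix, rows south-to-north, columns west-to-east.
#' @param origin_lat,origin_lon South-west corner of the grid, decimal degrees.
#' @param cellsize_arcmin Cell edge length in arcminutes (default 5, ~9.2 km).
#' @param variable Name of the variable held by the layer.
#' @param units Free-text units string.
#'
#' @return An object of class `env_raster`.
#' @export
env_raster <- function(values, origin_lat, origin_lon, cellsize_arcmin = 5,
                       variable = "layer", units = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (cellsize_arcmin <= 0) {
    stop_hexrich("`cellsize_arcmin` must be positive", "parameter_error")
  }
  structure(
    list(
      variable = variable, units = units,
      origin_lat = origin_lat, origin_lon = origin_lon,
      cellsize_arcmin = cellsize_arcmin,
      values = values
    ),
    class = "env_raster"
  )
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf(
    "<env_raster> %s [%s]: %d x %d cells of %.3g', origin (%.3f, %.3f)\n",
    x$variable, x$units, nrow(x$values), ncol(x$values),
    x$cellsize_arcmin, x$origin_lat, x$origin_lon
  ))
  invisible(x)
}

raster_cell_deg <- function(raster) raster$cellsize_arcmin / 60

# Centre coordinates of every row / column.
raster_lat_centers <- function(raster) {
  raster$origin_lat + (seq_len(nrow(raster$values)) - 0.5) * raster_cell_deg(raster)
}
raster_lon_centers <- function(raster) {
  raster$origin_lon + (seq_len(ncol(raster$values)) - 0.5) * raster_cell_deg(raster)
}

# Tidy view of a raster: one row per cell with centre coordinates.
#' Convert a raster to a tibble of cell centres
#'
#' @param x An [env_raster()].
#' @param ... Unused.
#' @return A tibble with `lat`, `lon`, `value`.
#' @export
as_tibble.env_raster <- function(x, ...) {
  lat <- raster_lat_centers(x)
  lon <- raster_lon_centers(x)
  lat_col <- rep(lat, times = length(lon))
  lon_col <- rep(lon, each = length(lat))
  tibble::tibble(lat = lat_col, lon = lon_col, value = as.vector(x$values))
}

#' Sample a raster at point locations
#'
#' Nearest-cell-centre lookup, the standard way of collating hexagon
#' mid-points with gridded environmental layers. Missing cells propagate as
#' `NA`.
#'
#' @param points Data frame with `lat` and `lon` columns (decimal degrees).
#' @param raster An [env_raster()].
#' @return Numeric vector of sampled values, one per point.
#' @export
sample_raster_at <- function(points, raster) {
  stopifnot(is.data.frame(points), all(c("lat", "lon") %in% names(points)))
  cs <- raster_cell_deg(raster)
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  i <- floor((points$lat - raster$origin_lat) / cs) + 1
  j <- floor((points$lon - raster$origin_lon) / cs) + 1
  # Points exactly on the top/right grid edge belong to the last cell.
  i[points$lat == raster$origin_lat + nr * cs] <- nr
  j[points$lon == raster$origin_lon + nc * cs] <- nc
  bad <- i < 1 | i > nr | j < 1 | j > nc | is.na(i) | is.na(j)
  if (any(bad)) {
    k <- which(bad)[1]
    stop_hexrich(
      sprintf(
        "point (%.4f, %.4f) lies outside the raster extent of '%s'",
        points$lat[k], points$lon[k], raster$variable
      ),
      "domain_error"
    )
  }
  raster$values[cbind(i, j)]
}

#' Write / read a raster as headered gridded text
#'
#' Plain-text interchange format: a small `key value` header (variable, units,
#' origin, cell size in arcminutes, dimensions, nodata sentinel) followed by
#' one space-separated row of values per grid row, northernmost row first.
#'
#' @param raster An [env_raster()].
#' @param path File path.
#' @param nodata Sentinel written in place of `NA` values.
#' @return `write_env_raster()` returns `path` invisibly; `read_env_raster()`
#'   returns an [env_raster()].
#' @export
write_env_raster <- function(raster, path, nodata = -9999) {
  vals <- raster$values
  vals[is.na(vals)] <- nodata
  header <- c(
    paste("variable", raster$variable),
    paste("units", raster$units),
    paste("origin_lat", format(raster$origin_lat, digits = 12)),
    paste("origin_lon", format(raster$origin_lon, digits = 12)),
    paste("cellsize_arcmin", format(raster$cellsize_arcmin, digits = 12)),
    paste("nrows", nrow(vals)),
    paste("ncols", ncol(vals)),
    paste("nodata", format(nodata, digits = 12))
  )
  rows <- apply(vals[rev(seq_len(nrow(vals))), , drop = FALSE], 1,
    paste,
    collapse = " "
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_env_raster
#' @export
read_env_raster <- function(path) {
  lines <- readLines(path)
  header <- lines[1:8]
  kv <- strsplit(header, " ", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]])
  nc <- as.integer(vals[["ncols"]])
  nodata <- as.numeric(vals[["nodata"]])
  body <- lines[-(1:8)]
  m <- matrix(
    scan(text = body, quiet = TRUE),
    nrow = nr, ncol = nc, byrow = TRUE
  )
  m <- m[rev(seq_len(nr)), , drop = FALSE]
  m[m == nodata] <- NA
  env_raster(
    m,
    origin_lat = as.numeric(vals[["origin_lat"]]),
    origin_lon = as.numeric(vals[["origin_lon"]]),
    cellsize_arcmin = as.numeric(vals[["cellsize_arcmin"]]),
    variable = vals[["variable"]], units = vals[["units"]]
  )
}

#' Ocean area of a latitudinal band
#'
#' Sums exact spherical zone areas of every ocean (`mask == 1`) raster cell
#' whose centre falls in the band and inside the study box. Used to normalise
#' band diversity by available ocean area.
#'
#' @param band_index 1-based band index (see [assign_band()]).
#' @param ocean_mask An [env_raster()] with values in `{0, 1}` (NA = land).
#' @param bbox Study bounding box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param band_width Band width in degrees (default 5).
#' @return Ocean area in km^2.
#' @export
band_ocean_area <- function(band_index, ocean_mask,
                            bbox = c(0, 90, 100, 180), band_width = 5) {
  cs <- raster_cell_deg(ocean_mask)
  lat <- raster_lat_centers(ocean_mask)
  lon <- raster_lon_centers(ocean_mask)
  band_lo <- (band_index - 1) * band_width
  band_hi <- band_index * band_width
  in_band <- lat >= band_lo & lat < band_hi & lat >= bbox[1] & lat <= bbox[2]
  in_lon <- lon >= bbox[3] & lon <= bbox[4]
  if (!any(in_band) || !any(in_lon)) {
    return(0)
  }
  # Per-cell zone area depends on the row latitude only.
  row_area <- zone_area_km2(lat[in_band] - cs / 2, lat[in_band] + cs / 2, 0, cs)
  ocean_per_row <- rowSums(
    ocean_mask$values[in_band, in_lon, drop = FALSE] == 1,
    na.rm = TRUE
  )
  sum(row_area * ocean_per_row)
}
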