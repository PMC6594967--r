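#' Equal-area hexagonal grids
#'
#' The local analysis unit is a hexagonal cell of roughly constant spherical
#' area (default 50,000 km^2). Cells are laid out as a pointy-top axial
#' tessellation in the plane of a Lambert azimuthal equal-area (LAEA)
#' projection centred on the study box; because the projection preserves
#' areas on the spherical Earth model, every hexagon has exactly the target
#' spherical area, and point-in-cell assignment reduces to exact axial
#' rounding (no gaps, no overlaps, deterministic boundary ties).
#'
#' @name hex_grid
NULL

# --- Lambert azimuthal equal-area projection (spherical form, km) -----------

laea_forward <- function(lat, lon, lat0, lon0, R = EARTH_RADIUS_KM) {
  phi <- deg2rad(lat)
  lam <- deg2rad(lon)
  phi0 <- deg2rad(lat0)
  lam0 <- deg2rad(lon0)
  dl <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  k <- sqrt(2 / denom)
  list(
    x = R * k * cos(phi) * sin(dl),
    y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  )
}

laea_inverse <- function(x, y, lat0, lon0, R = EARTH_RADIUS_KM) {
  phi0 <- deg2rad(lat0)
  lam0 <- deg2rad(lon0)
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * R)))
  sinc <- sin(c_ang)
  cosc <- cos(c_ang)
  phi <- ifelse(
    rho == 0, phi0,
    asin(pmax(-1, pmin(1, cosc * sin(phi0) + y * sinc * cos(phi0) / rho)))
  )
  lam <- ifelse(
    rho == 0, lam0,
    lam0 + atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc)
  )
  list(lat = rad2deg(phi), lon = rad2deg(lam))
}

# --- axial hexagon helpers (pointy-top) -------------------------------------

hex_center_xy <- function(q, r, hex_r) {
  list(x = hex_r * sqrt(3) * (q + r / 2), y = hex_r * 1.5 * r)
}

# Nearest hexagon via fractional axial coordinates + cube rounding. This is
# the exact point-location rule: every planar point belongs to exactly one
# hexagon, with deterministic resolution on shared edges.
hex_round <- function(x, y, hex_r) {
  qf <- (sqrt(3) / 3 * x - y / 3) / hex_r
  rf <- (2 / 3 * y) / hex_r
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf)
  ry <- round(yf)
  rz <- round(zf)
  dx <- abs(rx - xf)
  dy <- abs(ry - yf)
  dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

hex_cell_id <- function(q, r) sprintf("q%+04d_r%+04d", q, r)

#' Build the equal-area hexagonal grid over a study box
#'
#' @param target_area_km2 Target spherical cell area in km^2 (default 50,000).
#' @param bbox Study box `c(lat_min, lat_max, lon_min, lon_max)` in decimal
#'   degrees; default the NW Pacific + adjacent Arctic box 0-90 N, 100-180 E.
#' @param subgrid Sub-sampling resolution used to measure each boundary
#'   cell's area inside the box (midpoint rule on the equal-area plane).
#'
#' @return A `hex_grid` object: projection parameters, hexagon circumradius,
#'   and a `cells` tibble with `cell_id`, axial indices, centroid
#'   latitude/longitude, the (constant) spherical cell area `area_km2` and
#'   the clipped `area_in_bbox_km2`.
#' @export
build_hex_grid <- function(target_area_km2 = 50000,
                           bbox = c(0, 90, 100, 180),
                           subgrid = 64) {
  if (target_area_km2 <= 0) {
    stop_hexrich("`target_area_km2` must be positive", "parameter_error")
  }
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop_hexrich("degenerate bounding box", "parameter_error")
  }
  lat0 <- mean(bbox[1:2])
  lon0 <- mean(bbox[3:4])
  # Planar area equals spherical area under LAEA; hexagon area = 3*sqrt(3)/2 r^2.
  hex_r <- sqrt(2 * target_area_km2 / (3 * sqrt(3)))

  # Projected extent of the box boundary (densely sampled), padded by one cell.
  edge <- rbind(
    cbind(bbox[1], seq(bbox[3], bbox[4], length.out = 201)),
    cbind(bbox[2], seq(bbox[3], bbox[4], length.out = 201)),
    cbind(seq(bbox[1], bbox[2], length.out = 201), bbox[3]),
    cbind(seq(bbox[1], bbox[2], length.out = 201), bbox[4])
  )
  pe <- laea_forward(edge[, 1], edge[, 2], lat0, lon0)
  pad <- 2 * hex_r
  xr <- range(pe$x) + c(-pad, pad)
  yr <- range(pe$y) + c(-pad, pad)

  r_seq <- seq(floor(yr[1] / (1.5 * hex_r)) - 1, ceiling(yr[2] / (1.5 * hex_r)) + 1)
  # The centre x-coordinate is hex_r * sqrt(3) * (q + r/2), so the admissible
  # q range shifts with r.
  cand <- do.call(rbind, lapply(r_seq, function(rr) {
    q_lo <- floor(xr[1] / (sqrt(3) * hex_r) - rr / 2) - 1
    q_hi <- ceiling(xr[2] / (sqrt(3) * hex_r) - rr / 2) + 1
    data.frame(q = seq(q_lo, q_hi), r = rr)
  }))
  ctr <- hex_center_xy(cand$q, cand$r, hex_r)

  in_bbox <- function(lat, lon) {
    lat >= bbox[1] & lat <= bbox[2] & lon >= bbox[3] & lon <= bbox[4]
  }

  # Coarse overlap screen: centre + 6 vertices + 6 edge midpoints.
  frac_coarse <- overlap_fraction(cand$q, cand$r, ctr, hex_r, lat0, lon0,
    in_bbox,
    g = 16
  )
  hit <- frac_coarse > 0
  cand <- cand[hit, , drop = FALSE]
  ctr <- list(x = ctr$x[hit], y = ctr$y[hit])
  frac <- frac_coarse[hit]

  # Refine boundary cells with a finer midpoint subgrid.
  boundary <- frac < 1
  if (any(boundary)) {
    frac[boundary] <- overlap_fraction(
      cand$q[boundary], cand$r[boundary],
      list(x = ctr$x[boundary], y = ctr$y[boundary]),
      hex_r, lat0, lon0, in_bbox,
      g = subgrid
    )
  }
  keep2 <- frac > 0
  cand <- cand[keep2, , drop = FALSE]
  ctr <- list(x = ctr$x[keep2], y = ctr$y[keep2])
  frac <- frac[keep2]

  cen_ll <- laea_inverse(ctr$x, ctr$y, lat0, lon0)
  cells <- tibble::tibble(
    cell_id = hex_cell_id(cand$q, cand$r),
    q = cand$q, r = cand$r,
    centroid_lat = cen_ll$lat, centroid_lon = cen_ll$lon,
    area_km2 = target_area_km2,
    area_in_bbox_km2 = frac * target_area_km2
  ) |>
    dplyr::arrange(.data$cell_id)

  structure(
    list(
      lat0 = lat0, lon0 = lon0, hex_r = hex_r,
      target_area_km2 = target_area_km2, bbox = bbox,
      cells = cells
    ),
    class = "hex_grid"
  )
}

# Fraction of a hexagon's (planar = spherical) area that lies inside the
# study box, by a g x g midpoint subgrid over the hexagon bounding rectangle;
# points are kept when axial rounding maps them back to the same hexagon.
overlap_fraction <- function(q, r, ctr, hex_r, lat0, lon0, in_bbox, g) {
  n <- length(q)
  u <- (seq_len(g) - 0.5) / g
  ox <- rep((u * 2 - 1) * (sqrt(3) / 2) * hex_r, times = g)
  oy <- rep((u * 2 - 1) * hex_r, each = g)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    px <- ctr$x[i] + ox
    py <- ctr$y[i] + oy
    hr <- hex_round(px, py, hex_r)
    inside_hex <- hr$q == q[i] & hr$r == r[i]
    if (!any(inside_hex)) next
    ll <- laea_inverse(px[inside_hex], py[inside_hex], lat0, lon0)
    frac[i] <- sum(in_bbox(ll$lat, ll$lon)) / sum(inside_hex)
  }
  frac
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "<hex_grid> %d cells of %.0f km2 (LAEA centre %.1f N %.1f E, r = %.1f km)\n",
    nrow(x$cells), x$target_area_km2, x$lat0, x$lon0, x$hex_r
  ))
  invisible(x)
}

#' Hexagon vertices in geographic coordinates
#'
#' @param grid A [build_hex_grid()] result.
#' @param cell_id Character vector of cell ids (default: all cells).
#' @return A tibble with `cell_id`, `vertex` (1-6), `lat`, `lon`.
#' @export
hex_cell_vertices <- function(grid, cell_id = NULL) {
  cells <- grid$cells
  if (!is.null(cell_id)) cells <- cells[cells$cell_id %in% cell_id, ]
  th <- pi / 6 + (0:5) * pi / 3
  ctr <- hex_center_xy(cells$q, cells$r, grid$hex_r)
  out <- tidyr::expand_grid(i = seq_len(nrow(cells)), vertex = 1:6)
  vx <- ctr$x[out$i] + grid$hex_r * cos(th[out$vertex])
  vy <- ctr$y[out$i] + grid$hex_r * sin(th[out$vertex])
  ll <- laea_inverse(vx, vy, grid$lat0, grid$lon0)
  tibble::tibble(
    cell_id = cells$cell_id[out$i],
    vertex = out$vertex, lat = ll$lat, lon = ll$lon
  )
}

#' Assign point records to hexagonal cells
#'
#' Projects each point into the grid plane and locates its hexagon by exact
#' axial rounding (equivalently: the cell with the nearest centre in the
#' hexagonal metric). Boundary points resolve deterministically.
#'
#' @param records Data frame with `latitude` and `longitude` columns.
#' @param grid A [build_hex_grid()] result.
#' @return `records` with a `cell_id` column appended.
#' @export
assign_to_cell <- function(records, grid) {
  stopifnot(all(c("latitude", "longitude") %in% names(records)))
  p <- laea_forward(records$latitude, records$longitude, grid$lat0, grid$lon0)
  hr <- hex_round(p$x, p$y, grid$hex_r)
  dplyr::mutate(
    tibble::as_tibble(records),
    cell_id = hex_cell_id(hr$q, hr$r)
  )
}

#' Latitudinal band and depth-interval assignment
#'
#' Bands are half-open `[5k, 5k + 5)` degree intervals (top band closed at
#' 90); depth intervals are half-open `[100k, 100k + 100)` metre intervals
#' (top interval closed at 11,000 m).
#'
#' @param latitude Latitude in decimal degrees, within `[0, 90]`.
#' @param band_width Band width in degrees (default 5).
#' @param lat_max Top of the banded domain (default 90).
#' @return 1-based integer band index.
#' @export
assign_band <- function(latitude, band_width = 5, lat_max = 90) {
  if (any(is.na(latitude)) || any(latitude < 0 | latitude > lat_max)) {
    stop_hexrich("latitude outside [0, lat_max]", "domain_error")
  }
  n_band <- ceiling(lat_max / band_width)
  pmin(floor(latitude / band_width), n_band - 1) + 1L
}

#' @rdname assign_band
#' @param depth Depth in metres, within `[0, depth_max]`.
#' @param interval Depth interval width in metres (default 100).
#' @param depth_max Bottom of the binned domain (default 11,000 m).
#' @export
assign_depth_interval <- function(depth, interval = 100, depth_max = 11000) {
  if (any(is.na(depth)) || any(depth < 0 | depth > depth_max)) {
    stop_hexrich("depth outside [0, depth_max]", "domain_error")
  }
  n_int <- ceiling(depth_max / interval)
  pmin(floor(depth / interval), n_int - 1) + 1L
}

#' Export a hexagonal grid as GeoJSON
#'
#' Writes one polygon feature per cell with `cell_id`, spherical area and
#' clipped in-box area as properties.
#'
#' @param grid A [build_hex_grid()] result.
#' @param path Output file path.
#' @param properties Optional data frame keyed by `cell_id` with extra
#'   per-cell properties to attach.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path, properties = NULL) {
  verts <- hex_cell_vertices(grid)
  verts_by <- split(verts, verts$cell_id)
  cells <- grid$cells
  if (!is.null(properties)) {
    cells <- dplyr::left_join(cells, properties, by = "cell_id")
  }
  features <- lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$cell_id[i]
    v <- verts_by[[id]]
    ring <- cbind(v$lon, v$lat)
    ring <- rbind(ring, ring[1, ])
    props <- as.list(cells[i, setdiff(names(cells), c("q", "r")), drop = FALSE])
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = 8
  )
  invisible(path)
}
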