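#' Regular latitude-longitude grid with spherical cell areas
#'
#' Builds a global regular grid (the Earth-system-model output resolution is
#' 1.9 deg latitude x 2.5 deg longitude, i.e. 96 x 144; toy worlds use
#' coarser grids). Cell areas follow the exact spherical formula
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`, so the areas of a
#' full global grid sum to `4 * pi * R^2`.
#'
#' @param nlat,nlon Number of latitude and longitude cells.
#' @param radius_m Earth radius in metres.
#' @return An object of class `grid_spec`: a list with `nlat`, `nlon`,
#'   `radius_m` and `cells`, a tibble with one row per cell: `cell` (integer
#'   id, row-major from the south-west), `i` (lat index, south to north),
#'   `j` (lon index, west to east), `lat`, `lon` (centres), `lat_lo`,
#'   `lat_hi`, `lon_lo`, `lon_hi`, `area_m2`.
#' @examples
#' g <- grid_spec(30, 40)
#' sum(g$cells$area_m2) / (4 * pi * g$radius_m^2)
#' @export
grid_spec <- function(nlat, nlon, radius_m = 6.371e6) {
  stopifnot(nlat >= 2, nlon >= 2)
  lat_edges <- seq(-90, 90, length.out = nlat + 1)
  lon_edges <- seq(-180, 180, length.out = nlon + 1)
  dlam <- (lon_edges[2] - lon_edges[1]) * pi / 180

  ij <- tidyr::expand_grid(i = seq_len(nlat), j = seq_len(nlon))
  cells <- ij %>%
    mutate(
      cell = (.data$i - 1L) * nlon + .data$j,
      lat_lo = lat_edges[.data$i],
      lat_hi = lat_edges[.data$i + 1L],
      lon_lo = lon_edges[.data$j],
      lon_hi = lon_edges[.data$j + 1L],
      lat = (.data$lat_lo + .data$lat_hi) / 2,
      lon = (.data$lon_lo + .data$lon_hi) / 2,
      area_m2 = radius_m^2 * dlam *
        (sin(.data$lat_hi * pi / 180) - sin(.data$lat_lo * pi / 180))
    ) %>%
    select("cell", "i", "j", "lat", "lon", "lat_lo", "lat_hi",
           "lon_lo", "lon_hi", "area_m2") %>%
    arrange(.data$cell)

  structure(list(nlat = nlat, nlon = nlon, radius_m = radius_m,
                 cells = cells),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%.3g deg lat x %.3g deg lon)\n",
              x$nlat, x$nlon, 180 / x$nlat, 360 / x$nlon))
  invisible(x)
}

#' Locate points on a grid
#'
#' Maps lon/lat points to cell ids; longitudes are wrapped into
#' \[-180, 180).
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinates.
#' @return Integer vector of cell ids.
#' @export
grid_locate <- function(grid, lon, lat) {
  lon <- ((lon + 180) %% 360) - 180
  i <- pmin(pmax(findInterval(lat, seq(-90, 90, length.out = grid$nlat + 1),
                              rightmost.closed = TRUE), 1L), grid$nlat)
  j <- pmin(pmax(findInterval(lon, seq(-180, 180,
                                       length.out = grid$nlon + 1),
                              rightmost.closed = TRUE), 1L), grid$nlon)
  (i - 1L) * grid$nlon + j
}

# Queen (8-neighbour) adjacency with longitude wrap; returns a list of
# integer neighbour vectors indexed by cell id.
#' @noRd
grid_neighbours <- function(grid, queen = TRUE) {
  nlat <- grid$nlat; nlon <- grid$nlon
  offs <- if (queen) {
    cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(di = c(-1, 0, 0, 1), dj = c(0, -1, 1, 0))
  }
  lapply(seq_len(nlat * nlon), function(cell) {
    i <- (cell - 1L) %/% nlon + 1L
    j <- (cell - 1L) %% nlon + 1L
    ii <- i + offs[, "di"]
    jj <- (j - 1L + offs[, "dj"]) %% nlon + 1L
    keep <- ii >= 1L & ii <= nlat
    sort((ii[keep] - 1L) * nlon + jj[keep])
  })
}
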