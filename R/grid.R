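#' Lightweight regular lon/lat grid
#'
#' Rasters in this package are plain numeric matrices (rows = latitude bands,
#' north to south; columns = longitude) carried alongside a `bii_grid` object
#' holding the geotransform metadata and per-cell land areas. Cell areas are
#' computed on the sphere, so area weighting on the native grid is equivalent
#' in expectation to equal-area reprojection.
#'
#' @param nrow,ncol grid dimensions.
#' @param xmin,xmax,ymin,ymax bounding box in degrees.
#' @return object of class `bii_grid` with cell-centre coordinate vectors and a
#'   cell-area matrix in km^2.
#' @export
bii_grid <- function(nrow, ncol, xmin = 0, xmax = ncol, ymin = -nrow / 2,
                     ymax = nrow / 2) {
  stopifnot(nrow >= 1, ncol >= 1, xmax > xmin, ymax > ymin)
  dx <- (xmax - xmin) / ncol
  dy <- (ymax - ymin) / nrow
  lon <- xmin + (seq_len(ncol) - 0.5) * dx
  lat <- ymax - (seq_len(nrow) - 0.5) * dy # row 1 = northernmost band
  # spherical cell area, km^2 (R = 6371 km)
  r_km <- 6371
  band <- (pi / 180) * r_km^2 * dx *
    abs(sin((lat + dy / 2) * pi / 180) - sin((lat - dy / 2) * pi / 180))
  area <- matrix(rep(band, ncol), nrow = nrow, ncol = ncol)
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  structure(list(nrow = nrow, ncol = ncol, xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax, dx = dx, dy = dy,
                 lon = lon, lat = lat, cell_area = area),
            class = "bii_grid")
}

#' @export
print.bii_grid <- function(x, ...) {
  cat(sprintf("bii_grid: %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              x$nrow, x$ncol, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("nrow", "ncol", "xmin", "xmax", "ymin", "ymax")],
                   b[c("nrow", "ncol", "xmin", "xmax", "ymin", "ymax")]))
}

# matrix of cell-centre longitudes / latitudes matching raster layout
grid_lon_mat <- function(g) matrix(rep(g$lon, each = g$nrow), g$nrow, g$ncol)
grid_lat_mat <- function(g) matrix(rep(g$lat, g$ncol), g$nrow, g$ncol)
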