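# smooth random field on the toy grid: white noise passed through a few
# neighbour-averaging sweeps, then standardised
.smooth_field <- function(nr, nc, passes = 3) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (p in seq_len(passes)) {
    zp <- z
    up <- rbind(z[1, , drop = FALSE], z[-nr, , drop = FALSE])
    dn <- rbind(z[-1, , drop = FALSE], z[nr, , drop = FALSE])
    lf <- cbind(z[, 1, drop = FALSE], z[, -nc, drop = FALSE])
    rt <- cbind(z[, -1, drop = FALSE], z[, nc, drop = FALSE])
    z <- (zp + up + dn + lf + rt) / 5
  }
  (z - mean(z)) / stats::sd(z)
}

.LU_CLASSES <- c("primary", "secondary", "cropland", "pasture", "urban")

#' Generate the synthetic annual pressure world
#'
#' Builds the raw inputs of the projection pipeline on a toy unit-degree grid:
#' per-year land-use fraction rasters for the five coarse classes (summing to
#' one in every cell), annual forest-cover fractions consistent with primary +
#' secondary vegetation, human population density snapshots at 2000, 2005,
#' 2010 and 2015 growing exponentially at `hpd_growth`, static road-density
#' rasters at the 1 km and 50 km scales derived from random road segments,
#' region masks that partition the grid into contiguous longitude bands
#' (grouped into subregions), and a per-region GDP-per-capita table for the
#' first and last year. Regions named in `config$primary_loss` lose that
#' fraction of their initial primary vegetation linearly over the year range,
#' the loss converting to cropland; all other land-use change is absent, so a
#' world with an empty `primary_loss` and zero `hpd_growth` is static.
#'
#' @param config a [synthetic_world_config()].
#' @return object of class `bii_synthetic_world`: list with `grid`, `years`,
#'   `lu` (per-year named list of five fraction matrices), `forest` (per-year
#'   matrix), `hpd_snapshots` (named list at the four snapshot years),
#'   `road1`, `road50` (raw density matrices), `region_mask` (character
#'   matrix), `regions`, `subregion` (region -> subregion map), `gdp`
#'   (data.frame region/year/gdp_pc) and `ground_truth`.
#' @export
generate_pressure_stack <- function(config) {
  stopifnot(inherits(config, "bii_world_config"))
  set.seed(config$seed + 1L)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  g <- bii_grid(nr, nc)
  years <- seq(config$years[1], config$years[2])

  # region masks: contiguous longitude bands partitioning the grid
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  band <- cut(seq_len(nc), breaks = config$n_regions, labels = FALSE)
  region_mask <- matrix(regions[band[col(matrix(0, nr, nc))]], nr, nc)
  subregion <- stats::setNames(
    sprintf("SR%d", ceiling(seq_len(config$n_regions) / 4)), regions)

  miss <- setdiff(names(config$primary_loss), regions)
  if (length(miss)) {
    stop("generate_pressure_stack(): primary_loss names not in region set: ",
         paste(miss, collapse = ", "))
  }

  # base-year land-use fractions: softmax over smooth latent fields
  offs <- c(primary = 1.2, secondary = 0.2, cropland = -0.2, pasture = -0.4,
            urban = -2.5)
  lat <- lapply(.LU_CLASSES, function(k) 0.8 * .smooth_field(nr, nc))
  names(lat) <- .LU_CLASSES
  ex <- lapply(.LU_CLASSES, function(k) exp(offs[[k]] + lat[[k]]))
  tot <- Reduce(`+`, ex)
  base_lu <- lapply(ex, function(m) m / tot)
  names(base_lu) <- .LU_CLASSES

  # annual land use: linear primary -> cropland conversion in named regions
  span <- config$years[2] - config$years[1]
  lu <- list()
  forest <- list()
  for (y in years) {
    tau <- (y - config$years[1]) / span
    fr <- base_lu
    for (r in names(config$primary_loss)) {
      inr <- region_mask == r
      loss <- base_lu$primary * config$primary_loss[[r]] * tau
      fr$primary[inr] <- fr$primary[inr] - loss[inr]
      fr$cropland[inr] <- fr$cropland[inr] + loss[inr]
    }
    lu[[as.character(y)]] <- fr
    forest[[as.character(y)]] <- fr$primary + fr$secondary
  }

  # HPD snapshots: smooth lognormal base field, exponential growth
  hpd0 <- exp(1.5 + 1.2 * .smooth_field(nr, nc))
  hpd_snapshots <- lapply(c(2000, 2005, 2010, 2015), function(y)
    hpd0 * exp(config$hpd_growth * (y - 2000)))
  names(hpd_snapshots) <- c("2000", "2005", "2010", "2015")

  # static roads from random segments (grid coordinates, degrees)
  segs <- data.frame(x0 = stats::runif(config$n_road_segments, g$xmin, g$xmax),
                     y0 = stats::runif(config$n_road_segments, g$ymin, g$ymax),
                     x1 = stats::runif(config$n_road_segments, g$xmin, g$xmax),
                     y1 = stats::runif(config$n_road_segments, g$ymin, g$ymax))
  road1 <- road_density(segs, g, radius_km = 1)
  road50 <- road_density(segs, g, radius_km = 50)

  # GDP per capita: log-normal levels; growth optionally correlated with the
  # imposed primary loss so reporting power is testable in both regimes
  loss_vec <- stats::setNames(rep(0, config$n_regions), regions)
  loss_vec[names(config$primary_loss)] <- config$primary_loss
  gdp0 <- stats::rlnorm(config$n_regions, log(5000), 0.8)
  growth <- stats::rnorm(config$n_regions, 0.25, 0.25) -
    config$gdp_bii_correlation * scale_or_zero(loss_vec)
  gdp <- rbind(
    data.frame(region = regions, year = config$years[1], gdp_pc = gdp0),
    data.frame(region = regions, year = config$years[2],
               gdp_pc = gdp0 * exp(growth)))

  structure(list(
    grid = g, years = years, lu = lu, forest = forest,
    hpd_snapshots = hpd_snapshots, road1 = road1, road50 = road50,
    region_mask = region_mask, regions = regions, subregion = subregion,
    gdp = gdp,
    ground_truth = list(base_lu = base_lu, primary_loss = loss_vec,
                        hpd_growth = config$hpd_growth, gdp_growth = growth,
                        segments = segs)),
    class = "bii_synthetic_world")
}

# centre/scale that maps an all-constant vector to zeros instead of NaN
scale_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.bii_synthetic_world <- function(x, ...) {
  cat(sprintf(
    "bii_synthetic_world: %dx%d grid, years %d-%d, %d regions\n",
    x$grid$nrow, x$grid$ncol, min(x$years), max(x$years), length(x$regions)))
  invisible(x)
}
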