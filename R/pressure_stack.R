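#' Interpolate human population density between snapshot years
#'
#' Population snapshots exist for 2000, 2005, 2010 and 2015. After ln(x+1)
#' transformation, intervening years are obtained by linear interpolation of
#' the transformed value between the bracketing snapshots (i.e. populations
#' are assumed to grow exponentially): the value for 2006 is
#' 0.8 x value(2005) + 0.2 x value(2010) on the transformed scale. Snapshot
#' years are returned exactly; years outside [2000, 2015] are rejected rather
#' than extrapolated.
#'
#' @param snapshots named list of rasters (matrices) on the raw scale, names
#'   `"2000"`, `"2005"`, `"2010"`, `"2015"`.
#' @param year target year.
#' @return raster of ln(1+HPD) for the target year.
#' @export
interpolate_hpd <- function(snapshots, year) {
  yrs <- sort(as.numeric(names(snapshots)))
  if (!length(yrs) || anyNA(yrs)) {
    stop("interpolate_hpd(): snapshots must be named by year")
  }
  if (year < min(yrs) || year > max(yrs)) {
    stop("interpolate_hpd(): year ", year, " outside the snapshot range [",
         min(yrs), ", ", max(yrs), "]; no extrapolation")
  }
  if (year %in% yrs) return(ln1p(snapshots[[as.character(year)]]))
  lo <- max(yrs[yrs < year]); hi <- min(yrs[yrs > year])
  w <- (hi - year) / (hi - lo)
  w * ln1p(snapshots[[as.character(lo)]]) +
    (1 - w) * ln1p(snapshots[[as.character(hi)]])
}

#' Road density within a radius of each cell centre
#'
#' Total road length within `radius_km` of each cell's centre point, divided by
#' the area of that neighbourhood (km of road per km^2 of land), computed with
#' exact Euclidean segment-circle clipping on a projected toy grid (degrees are
#' scaled by `km_per_degree` on both axes). The layer is static across years.
#'
#' @param segments data.frame of road segments with columns `x0, y0, x1, y1`
#'   in grid (degree) coordinates; zero rows give a zero raster with a warning.
#' @param grid a [bii_grid()].
#' @param radius_km neighbourhood radius in km (1 and 50 in the pipeline).
#' @param km_per_degree flat projection scale, default 111.32.
#' @return raster (matrix) of road density.
#' @export
road_density <- function(segments, grid, radius_km,
                         km_per_degree = 111.32) {
  stopifnot(inherits(grid, "bii_grid"), radius_km > 0)
  dens <- matrix(0, grid$nrow, grid$ncol)
  if (is.null(segments) || nrow(segments) == 0) {
    warning("road_density(): no road segments; returning zero raster")
    return(dens)
  }
  cx <- grid_lon_mat(grid) * km_per_degree
  cy <- grid_lat_mat(grid) * km_per_degree
  for (s in seq_len(nrow(segments))) {
    ax <- segments$x0[s] * km_per_degree; ay <- segments$y0[s] * km_per_degree
    bx <- segments$x1[s] * km_per_degree; by <- segments$y1[s] * km_per_degree
    dx <- bx - ax; dy <- by - ay
    a2 <- dx * dx + dy * dy
    if (a2 == 0) next
    # |A + t(B-A) - C|^2 <= r^2, t in [0, 1]
    fx <- ax - cx; fy <- ay - cy
    b <- 2 * (fx * dx + fy * dy)
    c0 <- fx * fx + fy * fy - radius_km^2
    disc <- b * b - 4 * a2 * c0
    has <- disc > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- pmax((-b - sq) / (2 * a2), 0)
    t2 <- pmin((-b + sq) / (2 * a2), 1)
    len <- pmax(t2 - t1, 0) * sqrt(a2)
    dens <- dens + ifelse(has, len, 0)
  }
  dens / (pi * radius_km^2)
}

#' Harmonize predicted land-use fractions with observed forest cover
#'
#' Applies the two constraint rules that reconcile downscaled land-use
#' fractions with remotely-sensed forest cover, cellwise. Rule 1 (checked
#' first): where predicted primary habitat exceeds observed forest cover,
#' primary is reduced to the observed cover and the other four classes are
#' scaled by a common factor so the five-class total is preserved. Rule 2:
#' where predicted primary + secondary fall short of observed forest cover,
#' both are scaled proportionally so their sum matches it and the remaining
#' three classes are scaled by a common factor preserving the total. At most
#' one rule fires per cell. Forest cover above the five-class total is
#' treated as equal to the total. Where rule 1 fires in a cell whose four
#' non-primary fractions are all zero, the excess is assigned to secondary
#' vegetation (counted in attribute `n_excess_to_secondary`); where rule 2
#' fires with primary + secondary both zero, secondary receives the forest
#' cover directly.
#'
#' @param f_p,f_s,f_c,f_a,f_u fractions (matrices or vectors) of primary,
#'   secondary, cropland, pasture, urban; non-negative with cellwise sum <= 1.
#' @param gfc_forest observed forest-cover fraction in [0, 1].
#' @return list of the five adjusted fraction layers.
#' @export
harmonize_with_forest <- function(f_p, f_s, f_c, f_a, f_u, gfc_forest) {
  if (any(c(f_p, f_s, f_c, f_a, f_u) < 0, na.rm = TRUE)) {
    stop("harmonize_with_forest(): negative input fractions")
  }
  if (any(gfc_forest < 0 | gfc_forest > 1, na.rm = TRUE)) {
    stop("harmonize_with_forest(): forest cover outside [0, 1]")
  }
  tot <- f_p + f_s + f_c + f_a + f_u
  F_eff <- pmin(gfc_forest, tot)
  p <- f_p; s <- f_s; c <- f_c; a <- f_a; u <- f_u

  # rule 1: too much predicted primary
  r1 <- p > F_eff
  excess <- ifelse(r1, p - F_eff, 0)
  rest <- s + c + a + u
  scale1 <- ifelse(r1 & rest > 0, (rest + excess) / rest, 1)
  to_secondary <- r1 & rest <= 0
  p <- ifelse(r1, F_eff, p)
  s <- ifelse(to_secondary, s + excess, s * scale1)
  c <- c * scale1; a <- a * scale1; u <- u * scale1

  # rule 2: primary + secondary below observed forest (on cells rule 1 spared)
  ps <- f_p + f_s
  r2 <- !r1 & (ps < F_eff)
  up <- ifelse(r2 & ps > 0, F_eff / ps, 1)
  p <- p * up; s <- s * up
  s <- ifelse(r2 & ps == 0, F_eff, s)
  rem <- f_c + f_a + f_u
  target_rem <- tot - F_eff
  dn <- ifelse(r2 & rem > 0, target_rem / rem, 1)
  c <- ifelse(r2, f_c * dn, c)
  a <- ifelse(r2, f_a * dn, a)
  u <- ifelse(r2, f_u * dn, u)

  out <- list(primary = p, secondary = s, cropland = c, pasture = a, urban = u)
  attr(out, "n_excess_to_secondary") <- sum(to_secondary)
  attr(out, "rule") <- ifelse(r1, 1L, ifelse(r2, 2L, 0L))
  out
}

#' Synthetic land-use intensity allocation coefficients
#'
#' The intensity-allocation interface expects, for every coarse land-use class
#' and intensity level, an intercept and a slope on ln(1+HPD); shares are a
#' multinomial logit in these linear predictors. The real pipeline would plug
#' in externally fitted coefficients; this documented synthetic default gives
#' minimally-used shares that shrink, and intensively-used shares that grow,
#' with human population density.
#'
#' @return data.frame with columns land_use, intensity, intercept, slope.
#' @export
default_intensity_coefs <- function() {
  lu <- c("primary", "secondary", "cropland", "pasture", "urban")
  base <- expand.grid(land_use = lu,
                      intensity = c("minimal", "light", "intense"),
                      stringsAsFactors = FALSE)
  base$intercept <- c(minimal = 1.5, light = 0, intense = -1.5)[base$intensity]
  base$slope <- c(minimal = -0.25, light = 0.05, intense = 0.30)[base$intensity]
  # urban is rarely minimally used; primary skews strongly minimal
  base$intercept[base$land_use == "urban" & base$intensity == "minimal"] <- 0
  base$intercept[base$land_use == "primary" & base$intensity == "minimal"] <- 2.2
  base
}

#' Allocate land-use fractions across use intensities
#'
#' Splits each coarse land-use fraction into minimal / light / intense shares
#' with a multinomial logit in ln(1+HPD) (coefficients per land use and
#' intensity from `coefs`), then maps the land-use x intensity combinations to
#' the merged LUI classes of [lui_levels()] (primary keeps a minimal vs
#' light+intense split, secondary keeps all three intensities, cropland,
#' pasture and urban collapse across intensities). The per-class shares of
#' each land use sum exactly to its input fraction.
#'
#' @param fractions named list of the five land-use fraction rasters
#'   (harmonized).
#' @param ln1p_hpd raster of ln(1+HPD).
#' @param region_mask optional character raster; reserved for region-specific
#'   coefficient tables (the default coefficients are global).
#' @param coefs coefficient table, see [default_intensity_coefs()].
#' @return named list of merged-LUI fraction rasters.
#' @export
allocate_intensity <- function(fractions, ln1p_hpd, region_mask = NULL,
                               coefs = default_intensity_coefs()) {
  need <- c("land_use", "intensity", "intercept", "slope")
  if (!all(need %in% names(coefs))) {
    stop("allocate_intensity(): coefficient table must have columns ",
         paste(need, collapse = ", "))
  }
  want <- expand.grid(land_use = .LU_CLASSES,
                      intensity = c("minimal", "light", "intense"),
                      stringsAsFactors = FALSE)
  have <- paste(coefs$land_use, coefs$intensity)
  miss <- setdiff(paste(want$land_use, want$intensity), have)
  if (length(miss)) {
    stop("allocate_intensity(): missing coefficient entries: ",
         paste(miss, collapse = "; "))
  }
  if (any(!is.finite(coefs$intercept)) || any(!is.finite(coefs$slope))) {
    stop("allocate_intensity(): non-finite coefficients")
  }
  shares <- function(lu) {
    cf <- coefs[coefs$land_use == lu, ]
    ex <- lapply(c("minimal", "light", "intense"), function(iv) {
      row <- cf[cf$intensity == iv, ][1, ]
      exp(row$intercept + row$slope * ln1p_hpd)
    })
    tot <- ex[[1]] + ex[[2]] + ex[[3]]
    lapply(ex, function(e) e / tot)
  }
  sp <- shares("primary"); ss <- shares("secondary")
  out <- list(
    primary_minimal = fractions$primary * sp[[1]],
    primary_light_intense = fractions$primary * (sp[[2]] + sp[[3]]),
    secondary_minimal = fractions$secondary * ss[[1]],
    secondary_light = fractions$secondary * ss[[2]],
    secondary_intense = fractions$secondary * ss[[3]],
    cropland = fractions$cropland,
    pasture = fractions$pasture,
    urban = fractions$urban)
  out[lui_levels()]
}

#' Cap a raster to the covariate range observed in the modelling data
#'
#' Anthropogenic pressure layers are not permitted to exceed the ranges found
#' among the modelling sites, preventing the models from extrapolating beyond
#' the data. Values are clipped (on the transformed scale) to the persisted
#' [min, max] of the named variable.
#'
#' @param raster matrix of transformed covariate values.
#' @param caps named list of `c(min, max)` ranges (from a fit's `params$caps`).
#' @param variable cap entry to use.
#' @return clipped raster.
#' @export
cap_to_model_range <- function(raster, caps, variable) {
  if (is.null(caps[[variable]])) {
    stop("cap_to_model_range(): no caps stored for variable ", variable)
  }
  r <- caps[[variable]]
  pmin(pmax(raster, r[1]), r[2])
}

#' Build the model-ready annual pressure stack
#'
#' Runs the layer pipeline for each year: interpolates human population
#' density to the year on the ln(1+HPD) scale, harmonizes the five land-use
#' fractions with the year's observed forest cover, and allocates use
#' intensity to produce merged-LUI fraction rasters. Road densities are
#' static. The builder is deterministic: rebuilding from the same inputs
#' yields identical rasters.
#'
#' @param world raw layer provider, e.g. a [generate_pressure_stack()] world:
#'   needs `grid`, `years`, `lu`, `forest`, `hpd_snapshots`, `road1`,
#'   `road50`, `region_mask`, `subregion`, and optionally `gdp`.
#' @param intensity_coefs intensity-allocation coefficient table.
#' @param years years to build; default all of `world$years`.
#' @return object of class `bii_pressure_stack`: `grid`, `years`, per-year
#'   `fractions` (merged LUI classes) and `ln1p_hpd`, static `curt_road1`,
#'   `curt_road50`, plus region metadata carried through.
#' @export
build_pressure_stack <- function(world, intensity_coefs = default_intensity_coefs(),
                                 years = world$years) {
  stopifnot(all(years %in% world$years))
  fractions <- list(); hpd <- list()
  for (y in years) {
    key <- as.character(y)
    lh <- interpolate_hpd(world$hpd_snapshots, y)
    fr <- world$lu[[key]]
    hz <- harmonize_with_forest(fr$primary, fr$secondary, fr$cropland,
                                fr$pasture, fr$urban, world$forest[[key]])
    fractions[[key]] <- allocate_intensity(hz, lh, world$region_mask,
                                           intensity_coefs)
    hpd[[key]] <- lh
  }
  structure(list(grid = world$grid, years = years, fractions = fractions,
                 ln1p_hpd = hpd,
                 curt_road1 = curt(world$road1),
                 curt_road50 = curt(world$road50),
                 region_mask = world$region_mask,
                 subregion = world$subregion,
                 gdp = world$gdp),
            class = "bii_pressure_stack")
}

#' @export
print.bii_pressure_stack <- function(x, ...) {
  cat(sprintf("bii_pressure_stack: %dx%d grid, %d years (%d-%d), %d LUI classes\n",
              x$grid$nrow, x$grid$ncol, length(x$years), min(x$years),
              max(x$years), length(x$fractions[[1]])))
  invisible(x)
}
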