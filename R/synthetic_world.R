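#' Configuration for the synthetic assemblage-and-pressure world
#'
#' The generator emulates the structure of a spatial-comparison assemblage
#' database (multiple surveys, each comparing sites under different land-use
#' pressures) together with the annual gridded pressure layers needed to
#' project the fitted models: per-class land-use fractions, human population
#' density snapshots at 2000/2005/2010/2015, static two-scale road density,
#' annual forest-cover fractions, region masks and a per-region GDP table.
#' All randomness is controlled by `seed`; the realised coefficients and
#' random-effect draws are returned as ground truth so downstream estimates
#' can be checked against the values that actually generated the data.
#'
#' Effects are specified on the scales the models use: `lui_effects$abundance`
#' on the square-root rescaled-abundance scale (so the value is what the
#' abundance model's LUI coefficient should recover), `lui_effects$similarity`
#' on the adjusted-logit similarity scale. Continuous-pressure slopes apply to
#' the transformed covariates (ln(1+HPD), cube-root road densities).
#'
#' @param n_studies number of studies (surveys).
#' @param sites_per_study integer range `c(min, max)`; per-study site counts
#'   are drawn uniformly from this range. Minimum 2.
#' @param n_species_pool size of the global species pool.
#' @param grid_shape `c(rows, cols)` of the toy pressure grid (unit-degree
#'   cells).
#' @param years inclusive year range `c(first, last)`, within [2000, 2015].
#' @param lui_effects list with numeric vectors `abundance` and `similarity`,
#'   named by [lui_levels()]; reference class `primary_minimal` must be 0.
#' @param hpd_slope,road50_slope,road1_slope length-2 numeric vectors
#'   `c(abundance = ..., similarity = ...)`.
#' @param study_sd,block_sd,residual_sd non-negative SDs of the abundance
#'   channel (sqrt scale): study intercepts, block-within-study intercepts and
#'   site residuals.
#' @param sim_study_sd,sim_residual_sd non-negative SDs of the similarity
#'   channel (logit scale).
#' @param distance_decay positive rate (per degree) at which species occupancy
#'   probability decays with distance from the species' niche centre; drives
#'   compositional distance decay.
#' @param baseline_similarity expected native share of individuals at a
#'   pristine site (sets the similarity intercept), in (0, 1].
#' @param effort_varying_fraction fraction of studies whose sampling effort
#'   varies among sites (those studies report an effort-sensitive count
#'   metric and are excluded from similarity pairs).
#' @param class_weights positive sampling weights over [lui_levels()] used to
#'   allocate non-baseline sites to LUI classes.
#' @param n_regions number of regions (contiguous longitude bands) in the
#'   pressure world; regions are grouped into subregions of up to 4.
#' @param primary_loss named numeric vector, fraction of a region's initial
#'   primary-vegetation area lost linearly over the year range (e.g.
#'   `c(R01 = 0.10)`); lost area converts to cropland.
#' @param hpd_growth exponential growth rate of human population density per
#'   year.
#' @param n_road_segments number of random road segments on the toy grid.
#' @param gdp_bii_correlation strength of the (log-scale) association between
#'   regional GDP growth and imposed primary loss; 0 gives a null world.
#' @param seed integer seed (< 2^30); the pressure world uses `seed + 1`.
#' @return validated configuration object of class `bii_world_config`.
#' @export
synthetic_world_config <- function(
    n_studies = 30,
    sites_per_study = c(8, 15),
    n_species_pool = 500,
    grid_shape = c(20, 20),
    years = c(2001, 2012),
    lui_effects = NULL,
    hpd_slope = c(abundance = -0.03, similarity = -0.25),
    road50_slope = c(abundance = -0.03, similarity = -0.40),
    road1_slope = c(abundance = 0, similarity = -0.10),
    study_sd = 0.15, block_sd = 0.06, residual_sd = 0.06,
    sim_study_sd = 0.40, sim_residual_sd = 0.35,
    distance_decay = 1.5,
    baseline_similarity = 0.95,
    effort_varying_fraction = 0.25,
    class_weights = NULL,
    n_regions = 4,
    primary_loss = NULL,
    hpd_growth = 0.02,
    n_road_segments = 25,
    gdp_bii_correlation = 0,
    seed = 1) {
  lv <- lui_levels()
  if (is.null(lui_effects)) {
    lui_effects <- list(
      abundance = c(primary_minimal = 0, primary_light_intense = -0.05,
                    secondary_minimal = -0.08, secondary_light = -0.12,
                    secondary_intense = -0.18, cropland = -0.30,
                    pasture = -0.25, urban = -0.35),
      similarity = c(primary_minimal = 0, primary_light_intense = -0.4,
                     secondary_minimal = -0.6, secondary_light = -0.8,
                     secondary_intense = -1.1, cropland = -1.4,
                     pasture = -1.2, urban = -1.8))
  }
  if (is.null(class_weights)) {
    class_weights <- c(primary_minimal = 0.20, primary_light_intense = 0.10,
                       secondary_minimal = 0.10, secondary_light = 0.10,
                       secondary_intense = 0.10, cropland = 0.15,
                       pasture = 0.15, urban = 0.10)
  }
  if (is.null(primary_loss)) primary_loss <- stats::setNames(numeric(0), character(0))

  stopifnot(n_studies >= 2,
            length(sites_per_study) == 2, sites_per_study[1] >= 2,
            sites_per_study[2] >= sites_per_study[1],
            n_species_pool >= 50,
            length(grid_shape) == 2, all(grid_shape >= 1),
            length(years) == 2, years[2] > years[1],
            years[1] >= 2000, years[2] <= 2015,
            study_sd >= 0, block_sd >= 0, residual_sd >= 0,
            sim_study_sd >= 0, sim_residual_sd >= 0,
            distance_decay >= 0,
            baseline_similarity > 0, baseline_similarity <= 1,
            effort_varying_fraction >= 0, effort_varying_fraction <= 1,
            n_regions >= 1,
            hpd_growth >= 0,
            abs(seed) < 2^30)
  for (nm in c("abundance", "similarity")) {
    eff <- lui_effects[[nm]]
    miss <- setdiff(lv, names(eff))
    if (length(miss)) {
      stop("lui_effects$", nm, " missing classes: ", paste(miss, collapse = ", "))
    }
  }
  miss <- setdiff(lv, names(class_weights))
  if (length(miss)) stop("class_weights missing classes: ",
                         paste(miss, collapse = ", "))
  if (any(class_weights <= 0)) {
    stop("class_weights must be positive for every LUI class; a class with ",
         "zero weight would receive no sites and the models would be ",
         "inestimable: ",
         paste(names(class_weights)[class_weights <= 0], collapse = ", "))
  }
  if (length(primary_loss) && (any(primary_loss < 0) || any(primary_loss > 1))) {
    stop("primary_loss entries must lie in [0, 1]")
  }
  structure(list(
    n_studies = n_studies, sites_per_study = sites_per_study,
    n_species_pool = n_species_pool, grid_shape = grid_shape, years = years,
    lui_effects = lui_effects, hpd_slope = hpd_slope,
    road50_slope = road50_slope, road1_slope = road1_slope,
    study_sd = study_sd, block_sd = block_sd, residual_sd = residual_sd,
    sim_study_sd = sim_study_sd, sim_residual_sd = sim_residual_sd,
    distance_decay = distance_decay, baseline_similarity = baseline_similarity,
    effort_varying_fraction = effort_varying_fraction,
    class_weights = class_weights[lv],
    n_regions = n_regions, primary_loss = primary_loss,
    hpd_growth = hpd_growth, n_road_segments = n_road_segments,
    gdp_bii_correlation = gdp_bii_correlation, seed = as.integer(seed)),
    class = "bii_world_config")
}

# class-dependent log-mean pressure levels at sites (raw scales)
.HPD_MEANLOG <- c(primary_minimal = 0.5, primary_light_intense = 1.0,
                  secondary_minimal = 1.5, secondary_light = 2.0,
                  secondary_intense = 2.5, cropland = 3.0, pasture = 2.5,
                  urban = 5.5)
.R50_MEANLOG <- c(primary_minimal = -1.0, primary_light_intense = -0.5,
                  secondary_minimal = 0, secondary_light = 0.3,
                  secondary_intense = 0.6, cropland = 1.0, pasture = 0.8,
                  urban = 2.0)
.R1_MEANLOG <- .R50_MEANLOG - 1

# raw (land_use, use_intensity) pair consistent with a merged class,
# sampling among the raw combinations that merge to it
.raw_lui_pair <- function(class) {
  switch(class,
    primary_minimal = c("primary", "minimal"),
    primary_light_intense = c("primary", sample(c("light", "intense"), 1)),
    secondary_minimal = c("secondary", "minimal"),
    secondary_light = if (stats::runif(1) < 0.3) c("plantation", "minimal")
                      else c("secondary", "light"),
    secondary_intense = if (stats::runif(1) < 0.3)
                          c("plantation", sample(c("light", "intense"), 1))
                        else c("secondary", "intense"),
    c(class, sample(c("minimal", "light", "intense"), 1)))
}

#' Generate a synthetic assemblage table with known ground truth
#'
#' Site total abundance is generated on the square-root scale as
#' (intercept + study effect + block effect + LUI effect + pressure slopes +
#' residual)^2 and then partitioned across species. Species composition uses a
#' species-pool model: each study has a pool of native species whose occupancy
#' probability decays with distance from a random niche centre at rate
#' `distance_decay`, plus a pool of disturbance-adapted species absent from
#' pristine sites. The expected share of a site's individuals belonging to
#' native species follows an adjusted-logit linear model in the LUI class and
#' transformed pressures, so the asymmetric Jaccard similarity of generated
#' sites decays with pressure contrast and geographic distance the way the
#' similarity model assumes.
#'
#' @param config a [synthetic_world_config()].
#' @return list with `assemblages` (one row per site x species occurrence,
#'   columns per the assemblage CSV contract), `sites` (one row per site) and
#'   `ground_truth` (realised random effects, per-site linear predictors and
#'   native shares, and the effect values used).
#' @export
generate_assemblages <- function(config) {
  stopifnot(inherits(config, "bii_world_config"))
  set.seed(config$seed)
  lv <- lui_levels()
  g <- bii_grid(config$grid_shape[1], config$grid_shape[2])

  n_sites_study <- sample(seq(config$sites_per_study[1],
                              config$sites_per_study[2]), config$n_studies,
                          replace = TRUE)
  total_sites <- sum(n_sites_study)

  # global class allocation: one guaranteed minimally-used primary baseline
  # per study, remaining slots filled by largest-remainder quotas so every
  # class is represented whenever there are enough sites
  n_free <- total_sites - config$n_studies
  w <- config$class_weights / sum(config$class_weights)
  quota <- floor(n_free * w)
  rem <- n_free - sum(quota)
  if (rem > 0) {
    extra <- order(n_free * w - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  if (any(quota == 0) && n_free >= length(lv)) {
    # top up starved classes from the most abundant ones
    for (k in which(quota == 0)) {
      donor <- which.max(quota)
      quota[donor] <- quota[donor] - 1
      quota[k] <- quota[k] + 1
    }
  }
  if (any(quota[setdiff(lv, "primary_minimal")] == 0)) {
    stop("generate_assemblages(): configuration allocates zero sites to LUI ",
         "class(es) ",
         paste(names(quota)[quota == 0], collapse = ", "),
         "; increase sites_per_study or n_studies")
  }
  free_classes <- sample(rep(lv, quota))

  ab_eff <- config$lui_effects$abundance[lv]
  sim_eff <- config$lui_effects$similarity[lv]
  u_study <- stats::rnorm(config$n_studies, 0, config$study_sd)
  u_sim_study <- stats::rnorm(config$n_studies, 0, config$sim_study_sd)
  effort_varies <- stats::runif(config$n_studies) < config$effort_varying_fraction

  site_rows <- vector("list", config$n_studies)
  rec_rows <- vector("list", config$n_studies)
  block_effects <- list()
  free_ptr <- 0L
  z0 <- logit_adjusted(config$baseline_similarity)

  for (j in seq_len(config$n_studies)) {
    ns <- n_sites_study[j]
    study_id <- sprintf("ST%03d", j)
    cx <- stats::runif(1, g$xmin + 0.5, g$xmax - 0.5)
    cy <- stats::runif(1, g$ymin + 0.5, g$ymax - 0.5)
    lon <- cx + stats::runif(ns, -0.25, 0.25)
    lat <- cy + stats::runif(ns, -0.25, 0.25)

    cls <- c("primary_minimal",
             free_classes[free_ptr + seq_len(ns - 1L)])
    free_ptr <- free_ptr + ns - 1L
    cls <- sample(cls) # baseline position random among sites

    # regular spatial clustering into blocks: contiguous chunks along the
    # principal axis of the site cloud
    nb <- max(2L, ceiling(ns / 5))
    ord <- order(lon + lat)
    block <- integer(ns)
    block[ord] <- sort(rep(seq_len(nb), length.out = ns))
    v_block <- stats::rnorm(nb, 0, config$block_sd)
    block_effects[[study_id]] <- v_block

    hpd <- stats::rlnorm(ns, .HPD_MEANLOG[cls], 0.8)
    r50 <- stats::rlnorm(ns, .R50_MEANLOG[cls], 0.7)
    r1 <- stats::rlnorm(ns, .R1_MEANLOG[cls], 0.7)

    # environmental covariates: study-level base plus site noise
    env_base <- c(elev = stats::rnorm(1, 500, 300),
                  tmax_warm = stats::rnorm(1, 32, 2),
                  tmin_cold = stats::rnorm(1, 18, 3),
                  precip_wet = stats::rlnorm(1, 5.5, 0.3),
                  precip_dry = stats::rlnorm(1, 3.0, 0.5))
    env <- sapply(names(env_base), function(v)
      env_base[[v]] + stats::rnorm(ns, 0, abs(env_base[[v]]) * 0.05 + 1e-8))
    env <- matrix(env, nrow = ns,
                  dimnames = list(NULL, names(env_base))) # strip row names

    mle <- stats::rlnorm(ns, log(100), 0.8)
    mle[stats::runif(ns) < 0.1] <- NA_real_
    effort <- if (effort_varies[j]) stats::runif(ns, 0.5, 2) else rep(1, ns)
    metric <- if (effort_varies[j]) "count" else
      sample(c("count", "density"), 1)

    e_ab <- stats::rnorm(ns, 0, config$residual_sd)
    lp_mean <- 1 + u_study[j] + v_block[block] + ab_eff[cls] +
      config$hpd_slope[["abundance"]] * ln1p(hpd) +
      config$road50_slope[["abundance"]] * curt(r50) +
      config$road1_slope[["abundance"]] * curt(r1)
    lp_mean <- unname(lp_mean)
    lp <- pmax(lp_mean + e_ab, 0.05)
    total <- lp^2

    e_sim <- stats::rnorm(ns, 0, config$sim_residual_sd)
    z <- z0 + sim_eff[cls] +
      config$hpd_slope[["similarity"]] * ln1p(hpd) +
      config$road50_slope[["similarity"]] * curt(r50) +
      config$road1_slope[["similarity"]] * curt(r1) +
      u_sim_study[j] + e_sim
    rho <- pmin(pmax(inv_logit_adjusted(unname(z)), 0), 1)

    # species-pool composition
    pool <- sample.int(config$n_species_pool, 42L)
    natives <- pool[1:30]
    ruderals <- pool[31:42]
    nc_lon <- cx + stats::runif(30, -0.35, 0.35)
    nc_lat <- cy + stats::runif(30, -0.35, 0.35)

    rec_j <- vector("list", ns)
    rho_real <- numeric(ns)
    for (s in seq_len(ns)) {
      d_deg <- geosphere::distHaversine(cbind(lon[s], lat[s]),
                                        cbind(nc_lon, nc_lat)) / 111320
      q <- exp(-config$distance_decay * d_deg)
      pres <- stats::runif(30) < q
      if (!any(pres)) pres[which.max(q)] <- TRUE
      w_nat <- stats::rlnorm(sum(pres), 0, 0.6)
      rud_pres <- if (rho[s] < 1) stats::runif(12) < 0.7 else rep(FALSE, 12)
      if (!any(rud_pres)) {
        a_nat <- w_nat / sum(w_nat) * total[s]
        a_rud <- numeric(0)
        rho_real[s] <- 1
      } else {
        a_nat <- w_nat / sum(w_nat) * rho[s] * total[s]
        w_rud <- stats::rlnorm(sum(rud_pres), 0, 0.6)
        a_rud <- w_rud / sum(w_rud) * (1 - rho[s]) * total[s]
        rho_real[s] <- rho[s]
      }
      sp <- c(natives[pres], ruderals[rud_pres])
      ab <- c(a_nat, a_rud)
      raw <- .raw_lui_pair(cls[s])
      rec_j[[s]] <- data.frame(
        study_id = study_id,
        site_id = sprintf("%s-S%02d", study_id, s),
        block_id = sprintf("%s-B%d", study_id, block[s]),
        longitude = lon[s], latitude = lat[s],
        land_use = raw[1], use_intensity = raw[2],
        sampling_effort = effort[s],
        max_linear_extent_m = mle[s],
        metric = metric,
        species_id = sprintf("SP%04d", sp),
        abundance = if (metric == "count") ab * effort[s] else ab,
        elev = unname(env[s, "elev"]), tmax_warm = unname(env[s, "tmax_warm"]),
        tmin_cold = unname(env[s, "tmin_cold"]),
        precip_wet = unname(env[s, "precip_wet"]),
        precip_dry = unname(env[s, "precip_dry"]),
        stringsAsFactors = FALSE)
    }
    rec_rows[[j]] <- do.call(rbind, rec_j)
    site_rows[[j]] <- data.frame(
      study_id = study_id,
      site_id = sprintf("%s-S%02d", study_id, seq_len(ns)),
      block_id = sprintf("%s-B%d", study_id, block),
      longitude = lon, latitude = lat, lui = cls,
      hpd = hpd, road50 = r50, road1 = r1,
      sampling_effort = effort, metric = metric,
      lp_mean = unname(lp_mean), lp = unname(lp), total_abundance = total,
      rho_target = unname(rho), rho_realized = rho_real,
      stringsAsFactors = FALSE)
  }

  assemblages <- do.call(rbind, rec_rows)
  rownames(assemblages) <- NULL
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  ground_truth <- list(
    study_effects = stats::setNames(u_study, sprintf("ST%03d",
                                                     seq_len(config$n_studies))),
    sim_study_effects = stats::setNames(u_sim_study,
                                        sprintf("ST%03d",
                                                seq_len(config$n_studies))),
    block_effects = block_effects,
    lui_effects = config$lui_effects,
    slopes = list(hpd = config$hpd_slope, road50 = config$road50_slope,
                  road1 = config$road1_slope),
    baseline_similarity = config$baseline_similarity,
    sites = sites,
    config = config)
  list(assemblages = assemblages, sites = sites, ground_truth = ground_truth)
}
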