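#' Effort-correct and rescale total abundance within one study
#'
#' Site-level total abundance is the sum of abundance across all species
#' recorded at the site. If sampling effort varied among the study's sites and
#' abundance was reported in an effort-sensitive metric (e.g. a count of
#' individuals), abundance is first divided by sampling effort; totals are then
#' rescaled by the study maximum so the largest value is exactly 1, which
#' removes inter-study differences in units and taxonomic focus.
#'
#' @param records assemblage records of a single study (columns `site_id`,
#'   `abundance`, `sampling_effort`, optionally `metric`).
#' @param effort_sensitive logical; is the abundance metric effort-sensitive?
#'   Defaults to `TRUE` when the study's `metric` column equals `"count"`.
#' @return data.frame with one row per site: `site_id`, `total` (effort
#'   corrected) and `rescaled` (max = 1; all zero with a warning if every
#'   site total is zero).
#' @export
effort_correct_and_rescale <- function(records, effort_sensitive = NULL) {
  stopifnot(length(unique(records$study_id)) <= 1L)
  if (any(records$sampling_effort <= 0)) {
    stop("effort_correct_and_rescale(): sampling effort must be positive")
  }
  if (is.null(effort_sensitive)) {
    effort_sensitive <- if ("metric" %in% names(records))
      identical(unique(records$metric), "count") else TRUE
  }
  eff <- tapply(records$sampling_effort, records$site_id, function(x) x[1])
  tot <- tapply(records$abundance, records$site_id, sum)
  varying <- length(unique(signif(eff, 12))) > 1L
  if (varying && effort_sensitive) tot <- tot / eff
  m <- max(tot)
  if (m == 0) {
    warning("effort_correct_and_rescale(): all site totals are zero in study ",
            records$study_id[1])
    resc <- tot
  } else {
    resc <- tot / m
  }
  data.frame(site_id = names(tot), total = as.numeric(tot),
             rescaled = as.numeric(resc), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Asymmetric abundance-based Jaccard similarity
#'
#' The proportion of site j's individuals that belong to species also present
#' in the baseline site i. Unlike the classical Jaccard index the measure is
#' not symmetric in its arguments.
#'
#' @param counts_i,counts_j non-negative numeric vectors of abundances named
#'   by species id.
#' @return similarity in \[0, 1\], or `NA_real_` when site j has zero total
#'   abundance (such pairs are excluded downstream).
#' @export
#' @examples
#' asymmetric_jaccard(c(A = 1, B = 2), c(A = 3, C = 1)) # 0.75
asymmetric_jaccard <- function(counts_i, counts_j) {
  if (any(counts_i < 0, na.rm = TRUE) || any(counts_j < 0, na.rm = TRUE)) {
    stop("asymmetric_jaccard(): negative abundances")
  }
  tot_j <- sum(counts_j)
  if (!is.finite(tot_j) || tot_j == 0) return(NA_real_)
  sp_i <- names(counts_i)[counts_i > 0]
  shared <- sum(counts_j[names(counts_j) %in% sp_i])
  shared / tot_j
}

#' Gower environmental dissimilarity between two sites
#'
#' Mean over variables of |x_i - x_j| / range, with ranges computed once over
#' the modelling dataset; variables with zero range contribute 0.
#'
#' @param env_i,env_j numeric vectors of environmental covariates (same
#'   names/order).
#' @param ranges per-variable ranges (max - min over the modelling data).
#' @return dissimilarity in \[0, 1\]; `NA` if any value is missing.
#' @export
gower_env_distance <- function(env_i, env_j, ranges) {
  stopifnot(length(env_i) == length(env_j), length(ranges) == length(env_i))
  if (anyNA(env_i) || anyNA(env_j)) return(NA_real_)
  d <- abs(env_i - env_j) / ranges
  d[ranges == 0] <- 0
  mean(d)
}

.ENV_VARS <- c("elev", "tmax_warm", "tmin_cold", "precip_wet", "precip_dry")

# one row per site with site-level attributes taken from the first record
.site_table <- function(records) {
  first <- !duplicated(records$site_id)
  out <- records[first, c("study_id", "site_id", "block_id", "longitude",
                          "latitude", "land_use", "use_intensity",
                          "sampling_effort", "max_linear_extent_m",
                          intersect("metric", names(records)), .ENV_VARS)]
  out$lui <- merge_plantation_lui(out$land_use, out$use_intensity)
  rownames(out) <- NULL
  out
}

#' Build compositional-similarity pairs for one study
#'
#' For a study with at least one minimally-used primary-vegetation site (the
#' baseline), every baseline site i is compared with every other site j of the
#' same study (including other baselines). Studies whose sampling effort
#' varies among sites are excluded, as are studies without a baseline or
#' without coordinates. Pairs where site j has zero total abundance, or where
#' an environmental value is missing, are dropped and counted.
#'
#' @param records assemblage records of one study.
#' @param site_pressures data.frame `site_id`, `hpd`, `road50`, `road1` (raw
#'   scales).
#' @param median_mle median maximum linear extent (metres) of the full
#'   modelling dataset.
#' @param env_ranges named ranges of the five environmental covariates over
#'   the modelling dataset.
#' @param include_reciprocal_baselines include both directions (i -> j and
#'   j -> i) for baseline-baseline pairs; default `TRUE`.
#' @param min_distance_m floor for zero geographic distances, see
#'   [scaled_geo_distance()].
#' @return data.frame of similarity pairs with contrast class and covariates
#'   on the transformed (unstandardised) scale; zero rows when the study is
#'   ineligible. Attribute `n_dropped` counts pairs dropped for undefined
#'   similarity or missing environment.
#' @export
build_similarity_pairs <- function(records, site_pressures, median_mle,
                                   env_ranges,
                                   include_reciprocal_baselines = TRUE,
                                   min_distance_m = 1) {
  empty <- data.frame()
  sites <- .site_table(records)
  if (anyNA(sites$longitude) || anyNA(sites$latitude)) {
    message("build_similarity_pairs(): study ", sites$study_id[1],
            " excluded (missing coordinates)")
    return(empty)
  }
  if (length(unique(signif(sites$sampling_effort, 12))) > 1L) return(empty)
  base_idx <- which(sites$lui == "primary_minimal")
  if (!length(base_idx)) return(empty)

  counts <- split(stats::setNames(records$abundance, records$species_id),
                  records$site_id)
  counts <- lapply(counts, function(v) tapply(v, names(v), sum))
  pr <- site_pressures[match(sites$site_id, site_pressures$site_id), ]
  tr <- data.frame(ln1p_hpd = ln1p(pr$hpd), curt_road50 = curt(pr$road50),
                   curt_road1 = curt(pr$road1))
  smean <- mean(tr$ln1p_hpd)

  n <- nrow(sites)
  rows <- list(); dropped <- 0L
  for (i in base_idx) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (!include_reciprocal_baselines && j %in% base_idx && j < i) next
      s <- asymmetric_jaccard(counts[[sites$site_id[i]]],
                              counts[[sites$site_id[j]]])
      gow <- gower_env_distance(as.numeric(sites[i, .ENV_VARS]),
                                as.numeric(sites[j, .ENV_VARS]),
                                env_ranges[.ENV_VARS])
      if (is.na(s) || is.na(gow)) { dropped <- dropped + 1L; next }
      d <- geosphere::distHaversine(
        c(sites$longitude[i], sites$latitude[i]),
        c(sites$longitude[j], sites$latitude[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = sites$study_id[1],
        baseline_site = sites$site_id[i], site = sites$site_id[j],
        similarity = s,
        contrast = as.character(sites$lui[j]),
        ln_scaled_geo = scaled_geo_distance(d, median_mle, min_distance_m),
        curt_gower = curt(gow),
        ln1p_hpd_j = tr$ln1p_hpd[j], curt_road50_j = tr$curt_road50[j],
        curt_road1_j = tr$curt_road1[j],
        ln1p_hpd_diff = tr$ln1p_hpd[i] - tr$ln1p_hpd[j],
        curt_road50_diff = tr$curt_road50[i] - tr$curt_road50[j],
        curt_road1_diff = tr$curt_road1[i] - tr$curt_road1[j],
        study_mean_ln1p_hpd = smean,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "n_dropped") <- dropped
  out
}

.AB_COVARS <- c("ln1p_hpd", "curt_road50", "curt_road1", "study_mean_ln1p_hpd")
.SIM_COVARS <- c("ln_scaled_geo", "curt_gower",
                 "ln1p_hpd_j", "curt_road50_j", "curt_road1_j",
                 "ln1p_hpd_diff", "curt_road50_diff", "curt_road1_diff",
                 "study_mean_ln1p_hpd")

#' Prepare the site-level abundance modelling dataset
#'
#' Applies [merge_plantation_lui()], [effort_correct_and_rescale()] per study,
#' square-root transforms the rescaled totals, attaches the transformed
#' pressure covariates and the study-mean ln(1+HPD) control, and standardises
#' every continuous covariate (mean 0, SD 1 over the modelling rows). The
#' standardisation parameters and the covariate caps (per-variable min/max on
#' the transformed scale) are persisted for projection-time reuse.
#'
#' @param assemblages assemblage record table (see [generate_assemblages()]).
#' @param site_pressures data.frame `site_id`, `hpd`, `road50`, `road1`.
#' @return object of class `bii_model_data`: list with `data` (one row per
#'   site) and `params` (standardisation, caps).
#' @export
prepare_abundance_data <- function(assemblages, site_pressures) {
  per_study <- split(assemblages, assemblages$study_id)
  rows <- lapply(per_study, function(rec) {
    st <- .site_table(rec)
    ab <- effort_correct_and_rescale(rec)
    st$rescaled_total_abundance <- ab$rescaled[match(st$site_id, ab$site_id)]
    st
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$sqrt_response <- sqrt(d$rescaled_total_abundance)
  pr <- site_pressures[match(d$site_id, site_pressures$site_id), ]
  if (anyNA(pr$hpd)) stop("prepare_abundance_data(): sites without pressures")
  d$ln1p_hpd <- ln1p(pr$hpd)
  d$curt_road50 <- curt(pr$road50)
  d$curt_road1 <- curt(pr$road1)
  d$study_mean_ln1p_hpd <- stats::ave(d$ln1p_hpd, d$study_id)

  std <- lapply(stats::setNames(.AB_COVARS, .AB_COVARS),
                function(v) standardize_fit(d[[v]]))
  for (v in .AB_COVARS) d[[paste0(v, "_z")]] <- standardize_apply(d[[v]], std[[v]])
  caps <- lapply(stats::setNames(c("ln1p_hpd", "curt_road50", "curt_road1"),
                                 c("ln1p_hpd", "curt_road50", "curt_road1")),
                 function(v) range(d[[v]]))
  structure(list(data = d,
                 params = list(standardize = std, caps = caps,
                               covariates = .AB_COVARS)),
            class = "bii_model_data")
}

#' Prepare the compositional-similarity modelling dataset
#'
#' Computes the dataset-wide median maximum linear extent and environmental
#' ranges, builds within-study similarity pairs against minimally-used
#' primary-vegetation baselines via [build_similarity_pairs()], logit-adjusts
#' the response and standardises all continuous covariates, persisting the
#' parameters (including Gower ranges and the median sampling grain) for
#' projection.
#'
#' @inheritParams prepare_abundance_data
#' @inheritParams build_similarity_pairs
#' @return object of class `bii_model_data` with pair-level `data` and
#'   `params`.
#' @export
prepare_similarity_data <- function(assemblages, site_pressures,
                                    include_reciprocal_baselines = TRUE,
                                    min_distance_m = 1) {
  median_mle <- stats::median(
    assemblages$max_linear_extent_m[!duplicated(assemblages$site_id)],
    na.rm = TRUE)
  if (!is.finite(median_mle) || median_mle <= 0) {
    stop("prepare_similarity_data(): no usable maximum linear extents")
  }
  sites_all <- .site_table(assemblages)
  env_ranges <- vapply(.ENV_VARS, function(v)
    diff(range(sites_all[[v]], na.rm = TRUE)), numeric(1))

  per_study <- split(assemblages, assemblages$study_id)
  pairs <- lapply(per_study, build_similarity_pairs,
                  site_pressures = site_pressures, median_mle = median_mle,
                  env_ranges = env_ranges,
                  include_reciprocal_baselines = include_reciprocal_baselines,
                  min_distance_m = min_distance_m)
  n_dropped <- sum(vapply(pairs, function(p)
    if (is.null(attr(p, "n_dropped"))) 0L else attr(p, "n_dropped"),
    integer(1)))
  pairs <- pairs[vapply(pairs, nrow, integer(1)) > 0]
  if (!length(pairs)) stop("prepare_similarity_data(): no eligible studies")
  d <- do.call(rbind, pairs)
  rownames(d) <- NULL
  d$logit_similarity <- logit_adjusted(d$similarity)
  d$contrast <- factor(d$contrast, levels = lui_levels())

  std <- lapply(stats::setNames(.SIM_COVARS, .SIM_COVARS),
                function(v) standardize_fit(d[[v]]))
  for (v in .SIM_COVARS) d[[paste0(v, "_z")]] <- standardize_apply(d[[v]], std[[v]])
  capvars <- c("ln1p_hpd_j", "curt_road50_j", "curt_road1_j",
               "ln1p_hpd_diff", "curt_road50_diff", "curt_road1_diff")
  caps <- lapply(stats::setNames(capvars, capvars), function(v) range(d[[v]]))
  structure(list(data = d,
                 params = list(standardize = std, caps = caps,
                               covariates = .SIM_COVARS,
                               median_mle = median_mle,
                               env_ranges = env_ranges,
                               min_distance_m = min_distance_m,
                               n_dropped = n_dropped)),
            class = "bii_model_data")
}
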