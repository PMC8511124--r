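# covariate rows for one merged-LUI class over all cells of a stack year.
# All covariates pass through the same cap -> standardise path as the
# baseline, so a pristine cell reproduces the baseline exactly.
.projection_newdata <- function(fit, stack, year, class) {
  key <- as.character(year)
  p <- fit$params
  std <- p$standardize
  capz <- function(x, var) {
    v <- if (!is.null(p$caps[[var]])) cap_to_model_range(x, p$caps, var) else x
    standardize_apply(v, std[[var]])
  }
  hpd <- as.vector(stack$ln1p_hpd[[key]])
  r50 <- as.vector(stack$curt_road50)
  r1 <- as.vector(stack$curt_road1)
  if (fit$kind == "abundance") {
    nd <- data.frame(
      lui = class,
      ln1p_hpd_z = capz(hpd, "ln1p_hpd"),
      curt_road50_z = capz(r50, "curt_road50"),
      curt_road1_z = capz(r1, "curt_road1"),
      study_mean_ln1p_hpd_z = 0)
  } else {
    nd <- data.frame(
      contrast = class,
      # baseline geometry: geographic distance at the median sampling grain
      # (ln ratio 0) and zero environmental distance
      ln_scaled_geo_z = standardize_apply(0, std$ln_scaled_geo),
      curt_gower_z = standardize_apply(0, std$curt_gower),
      ln1p_hpd_j_z = capz(hpd, "ln1p_hpd_j"),
      curt_road50_j_z = capz(r50, "curt_road50_j"),
      curt_road1_j_z = capz(r1, "curt_road1_j"),
      ln1p_hpd_diff_z = capz(-hpd, "ln1p_hpd_diff"),
      curt_road50_diff_z = capz(-r50, "curt_road50_diff"),
      curt_road1_diff_z = capz(-r1, "curt_road1_diff"),
      study_mean_ln1p_hpd_z = 0)
  }
  nd
}

.natural_scale <- function(kind, eta) {
  if (kind == "abundance") pmax(eta, 0)^2 else inv_logit_adjusted(eta)
}

#' Modelled prediction for the baseline (reference) condition
#'
#' The reference condition is minimally-used primary vegetation with zero
#' human population density and zero road density; for compositional
#' similarity the baseline pair additionally has zero environmental distance
#' and a geographic distance equal to the median sampling grain of the
#' modelling dataset. Control variables are set to zero (the covariate mean).
#' The prediction uses fixed effects only and is returned on the natural
#' scale: squared for abundance, inverse adjusted logit for similarity.
#' Baseline covariates pass through the same cap-and-standardise path as
#' projected cells, so a cell at baseline conditions has a relative
#' prediction of exactly 1.
#'
#' @param fit a [bii_fit] (or artifact read with [read_bii_artifact()]).
#' @return scalar baseline prediction on the natural scale.
#' @export
baseline_prediction <- function(fit) {
  p <- fit$params
  if (is.null(p$standardize)) {
    stop("baseline_prediction(): fit carries no standardisation parameters")
  }
  zero_stack <- list(
    ln1p_hpd = stats::setNames(list(matrix(0, 1, 1)), "0"),
    curt_road50 = matrix(0, 1, 1), curt_road1 = matrix(0, 1, 1))
  nd <- .projection_newdata(fit, zero_stack, 0, "primary_minimal")
  eta <- drop(.fixed_design(fit, nd) %*% fit$fixef)
  unname(.natural_scale(fit$kind, eta))
}

#' Project a component model over a pressure stack for one year
#'
#' For every cell the fixed-effect prediction is computed per merged-LUI class
#' (with the cell's capped, standardised pressure covariates and random
#' effects at zero), back-transformed to the natural scale, combined across
#' classes weighted by the cell's class fractions, and expressed relative to
#' [baseline_prediction()]. Cells with zero total land fraction are `NA`.
#'
#' @param fit a [bii_fit].
#' @param stack a [build_pressure_stack()] result.
#' @param year year to project (must be in the stack).
#' @param weighting `"natural"` combines class predictions on the natural
#'   (back-transformed) scale — the area-mixture interpretation of fractional
#'   cells; `"link"` averages linear predictors before back-transformation.
#' @return raster (matrix) of relative predictions.
#' @export
project_model <- function(fit, stack, year,
                          weighting = c("natural", "link")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(stack, "bii_pressure_stack"))
  if (!year %in% stack$years) stop("project_model(): year ", year,
                                   " not in the stack")
  key <- as.character(year)
  fr <- stack$fractions[[key]]
  present <- names(fr)[vapply(fr, function(m) any(m > 0), logical(1))]
  missing_cls <- setdiff(present, fit$xlev[[fit$lui_var]])
  if (length(missing_cls)) {
    stop("project_model(): LUI class(es) absent from the fitted model: ",
         paste(missing_cls, collapse = ", "))
  }
  base <- baseline_prediction(fit)
  n <- stack$grid$nrow * stack$grid$ncol
  tot <- Reduce(`+`, fr)
  acc <- numeric(n)
  for (cls in present) {
    w <- as.vector(fr[[cls]])
    idx <- w > 0
    if (!any(idx)) next
    nd <- .projection_newdata(fit, stack, year, cls)
    eta <- drop(.fixed_design(fit, nd[idx, , drop = FALSE]) %*% fit$fixef)
    val <- if (weighting == "natural") .natural_scale(fit$kind, eta) else eta
    acc[idx] <- acc[idx] + w[idx] * val
  }
  tv <- as.vector(tot)
  out <- ifelse(tv > 0, acc / tv, NA_real_)
  if (weighting == "link") out <- .natural_scale(fit$kind, out)
  matrix(out / base, stack$grid$nrow, stack$grid$ncol)
}

#' Compose BII from the relative abundance and similarity projections
#'
#' BII is the cellwise product of the relative total-abundance and relative
#' compositional-similarity rasters. Values may exceed 1 (abundance of
#' originally-present species can increase); they cannot be negative.
#'
#' @param rel_abundance,rel_similarity rasters from [project_model()] on the
#'   same grid and year.
#' @param grid the shared [bii_grid()].
#' @param year the projection year.
#' @return object of class `bii_raster`: list with `year`, `grid`, `bii` and
#'   the two component rasters.
#' @export
compute_bii <- function(rel_abundance, rel_similarity, grid, year) {
  if (!identical(dim(rel_abundance), dim(rel_similarity)) ||
      !all(dim(rel_abundance) == c(grid$nrow, grid$ncol))) {
    stop("compute_bii(): rasters and grid have mismatched dimensions")
  }
  structure(list(year = year, grid = grid,
                 bii = rel_abundance * rel_similarity,
                 rel_abundance = rel_abundance,
                 rel_similarity = rel_similarity),
            class = "bii_raster")
}

#' Project BII rasters for a span of years
#'
#' Convenience wrapper: projects both component models for every year of the
#' stack and composes the annual BII rasters.
#'
#' @param abundance_fit,similarity_fit the two [bii_fit] objects.
#' @param stack a [build_pressure_stack()] result.
#' @param years years to project, default all stack years.
#' @param weighting see [project_model()].
#' @return named list (by year) of `bii_raster` objects.
#' @export
project_bii <- function(abundance_fit, similarity_fit, stack,
                        years = stack$years, weighting = "natural") {
  out <- lapply(years, function(y) {
    ra <- project_model(abundance_fit, stack, y, weighting)
    rs <- project_model(similarity_fit, stack, y, weighting)
    compute_bii(ra, rs, stack$grid, y)
  })
  stats::setNames(out, as.character(years))
}

#' @export
print.bii_raster <- function(x, ...) {
  cat(sprintf("bii_raster %d: mean %.3f, range [%.3f, %.3f]\n", x$year,
              mean(x$bii, na.rm = TRUE), min(x$bii, na.rm = TRUE),
              max(x$bii, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.bii_raster <- function(x, which = c("bii", "rel_abundance",
                                         "rel_similarity"), ...) {
  which <- match.arg(which)
  z <- x[[which]]
  graphics::image(x$grid$lon, rev(x$grid$lat), t(z[nrow(z):1, , drop = FALSE]),
                  xlab = "longitude", ylab = "latitude",
                  main = sprintf("%s, %d", which, x$year), ...)
  invisible(x)
}
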