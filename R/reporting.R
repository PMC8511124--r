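#' Area-weighted regional summary of a BII raster
#'
#' Average BII per region is the cell-area-weighted mean of the modelled
#' (non-missing) cells intersecting the region; weighting by spherical cell
#' area on the native grid plays the role of equal-area reprojection.
#' Primary-vegetation area is the sum of primary fraction x cell area when a
#' primary-fraction raster is supplied. The included-area fraction reports how
#' much of the region's area carried a modelled value.
#'
#' @param bii a `bii_raster` (or plain matrix) of BII values.
#' @param region_mask character raster of region ids, same grid.
#' @param cell_area raster of cell areas (km^2); defaults to the grid's.
#' @param primary_fraction optional raster of primary-vegetation fraction.
#' @return data.frame: region, year, mean_bii, primary_area, included_fraction.
#'   Empty regions yield `NA` summaries.
#' @export
aggregate_region <- function(bii, region_mask, cell_area = NULL,
                             primary_fraction = NULL) {
  if (inherits(bii, "bii_raster")) {
    if (is.null(cell_area)) cell_area <- bii$grid$cell_area
    year <- bii$year
    values <- bii$bii
  } else {
    year <- NA_integer_
    values <- bii
  }
  if (is.null(cell_area)) stop("aggregate_region(): cell_area required")
  if (!identical(dim(values), dim(region_mask))) {
    stop("aggregate_region(): raster and mask have mismatched dimensions")
  }
  regions <- sort(unique(as.vector(region_mask)))
  rows <- lapply(regions, function(r) {
    inr <- region_mask == r
    ok <- inr & !is.na(values)
    if (!any(ok)) {
      message("aggregate_region(): region ", r, " has no modelled cells")
      return(data.frame(region = r, year = year, mean_bii = NA_real_,
                        primary_area = NA_real_, included_fraction = 0))
    }
    data.frame(
      region = r, year = year,
      mean_bii = sum(values[ok] * cell_area[ok]) / sum(cell_area[ok]),
      primary_area = if (is.null(primary_fraction)) NA_real_ else
        sum(primary_fraction[ok] * cell_area[ok]),
      included_fraction = sum(cell_area[ok]) / sum(cell_area[inr]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log response ratio of end versus start values
#'
#' `ln(value_end / value_start)`: zero means no change, negative a decline.
#' Non-positive inputs give `NA` with a warning.
#'
#' @param start,end positive summary values (e.g. regional mean BII in the
#'   first and last year).
#' @return numeric vector of log response ratios.
#' @export
log_response_ratio <- function(start, end) {
  bad <- !is.na(start) & !is.na(end) & (start <= 0 | end <= 0)
  if (any(bad)) {
    warning("log_response_ratio(): non-positive values give NA")
  }
  out <- log(end / start)
  out[bad] <- NA_real_
  out
}

#' Wilcoxon signed-rank test of regional BII trends
#'
#' Tests whether the log response ratios across regions are centred on zero.
#' Zeros are dropped (signed-rank convention); an all-zero input returns
#' p = 1 by convention.
#'
#' @param lrr numeric vector of per-region log response ratios (`NA` dropped).
#' @return object of class `bii_trend_test`: list with `median`, `V`, `p`,
#'   `n` (non-missing), `n_zero`.
#' @export
trend_test <- function(lrr) {
  lrr <- lrr[!is.na(lrr)]
  if (length(lrr) < 2) stop("trend_test(): need at least 2 non-missing values")
  med <- stats::median(lrr)
  nz <- lrr[lrr != 0]
  if (!length(nz)) {
    message("trend_test(): all log response ratios are zero; p = 1")
    res <- list(median = med, V = NA_real_, p = 1, n = length(lrr),
                n_zero = length(lrr))
    class(res) <- "bii_trend_test"
    return(res)
  }
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = FALSE,
                                            correct = TRUE))
  res <- list(median = med, V = unname(wt$statistic), p = wt$p.value,
              n = length(lrr), n_zero = length(lrr) - length(nz))
  class(res) <- "bii_trend_test"
  res
}

#' @export
print.bii_trend_test <- function(x, ...) {
  cat(sprintf("trend across %d regions: median L = %.4g, V = %s, p = %.3g\n",
              x$n, x$median, format(x$V), x$p))
  invisible(x)
}

#' Build the per-region trend table
#'
#' Joins first-year and last-year regional summaries with the GDP table into
#' one row per region: the BII log response ratio, the GDP-per-capita log
#' response ratio, log10 GDP at the start year, region area and included-area
#' fraction.
#'
#' @param summary_start,summary_end [aggregate_region()] rows for the first
#'   and last year.
#' @param gdp data.frame region/year/gdp_pc with both years.
#' @param subregion named map region -> subregion.
#' @param centroids optional data.frame region/lon/lat for spatial
#'   diagnostics.
#' @return data.frame of trend rows.
#' @export
build_trend_table <- function(summary_start, summary_end, gdp = NULL,
                              subregion = NULL, centroids = NULL) {
  stopifnot(identical(summary_start$region, summary_end$region))
  out <- data.frame(
    region = summary_start$region,
    lrr = log_response_ratio(summary_start$mean_bii, summary_end$mean_bii),
    included_fraction = summary_start$included_fraction,
    stringsAsFactors = FALSE)
  if (!is.null(gdp)) {
    y0 <- min(gdp$year); y1 <- max(gdp$year)
    g0 <- gdp$gdp_pc[gdp$year == y0][match(out$region,
                                           gdp$region[gdp$year == y0])]
    g1 <- gdp$gdp_pc[gdp$year == y1][match(out$region,
                                           gdp$region[gdp$year == y1])]
    out$gdp_lrr <- log_response_ratio(g0, g1)
    out$log10_gdp_start <- log10(g0)
  }
  if (!is.null(subregion)) out$subregion <- unname(subregion[out$region])
  if (!is.null(centroids)) {
    m <- match(out$region, centroids$region)
    out$lon <- centroids$lon[m]
    out$lat <- centroids$lat[m]
  }
  out
}

#' Association between BII trends and GDP across regions
#'
#' Linear mixed model of the per-region BII log response ratio on a GDP
#' predictor with subregion as a random intercept (accounting for spatial
#' autocorrelation among neighbouring regions). Simulated-free residuals are
#' screened for residual spatial autocorrelation with Moran's I
#' (inverse-distance weights on region centroids); when the diagnostic flags
#' autocorrelation (p < 0.05) and coordinates are available, a generalized
#' least-squares stage with a Gaussian distance-decay correlation structure
#' (and fixed subregion effects) is fitted instead. A singular subregion
#' random effect falls back to fixed subregion effects. Regions can be
#' filtered to those with at least `min_included_fraction` of their area
#' modelled.
#'
#' @param trends data.frame from [build_trend_table()] (needs `lrr`, the
#'   predictor column, `subregion`; `lon`/`lat` for spatial diagnostics).
#' @param predictor `"gdp_lrr"` (change in GDP per capita) or
#'   `"log10_gdp_start"`.
#' @param min_included_fraction optional area filter in [0, 1].
#' @param spatial_correction apply the GLS stage when Moran's I flags
#'   autocorrelation (`"auto"`), always (`TRUE`) or never (`FALSE`).
#' @return object of class `bii_gdp_fit`: estimate, se, t, p for the
#'   predictor, the Moran diagnostic, the method used and the sample size.
#' @export
gdp_association <- function(trends, predictor = "gdp_lrr",
                            min_included_fraction = NULL,
                            spatial_correction = "auto") {
  stopifnot(predictor %in% names(trends))
  d <- trends[!is.na(trends$lrr) & !is.na(trends[[predictor]]), , drop = FALSE]
  if (!is.null(min_included_fraction)) {
    d <- d[d$included_fraction >= min_included_fraction, , drop = FALSE]
  }
  if (is.null(d$subregion)) stop("gdp_association(): subregion column required")
  if (length(unique(d$subregion)) < 2) {
    stop("gdp_association(): need at least 2 subregions")
  }
  d$x <- d[[predictor]]
  if (stats::sd(d$x) == 0) {
    stop("gdp_association(): predictor ", predictor, " is constant")
  }
  X <- cbind(1, d$x)
  if (qr(X)$rank < 2) {
    stop("gdp_association(): collinear design for predictor ", predictor)
  }

  method <- "lmm"
  fit <- tryCatch(
    suppressMessages(lme4::lmer(lrr ~ x + (1 | subregion), data = d,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore"))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    method <- "lm_fixed_subregion"
    fit <- stats::lm(lrr ~ x + subregion, data = d)
    ct <- summary(fit)$coefficients
    est <- ct["x", ]
    resid <- stats::residuals(fit)
  } else {
    ct <- summary(fit)$coefficients
    est <- c(ct["x", "Estimate"], ct["x", "Std. Error"], ct["x", "t value"],
             2 * stats::pnorm(-abs(ct["x", "t value"])))
    resid <- stats::residuals(fit)
  }
  if (method == "lm_fixed_subregion") {
    est <- c(est[["Estimate"]], est[["Std. Error"]], est[["t value"]],
             est[["Pr(>|t|)"]])
  }

  moran <- NULL
  if (!is.null(d$lon) && !is.null(d$lat) && nrow(d) >= 5) {
    dm <- as.matrix(stats::dist(cbind(d$lon, d$lat)))
    w <- 1 / dm; diag(w) <- 0; w[!is.finite(w)] <- 0
    moran <- tryCatch(ape::Moran.I(resid, w), error = function(e) NULL)
  }
  do_gls <- isTRUE(spatial_correction) ||
    (identical(spatial_correction, "auto") && !is.null(moran) &&
       moran$p.value < 0.05)
  if (do_gls && !is.null(d$lon)) {
    gfit <- tryCatch(
      nlme::gls(lrr ~ x + subregion, data = d,
                correlation = nlme::corGaus(form = ~ lon + lat,
                                            nugget = TRUE)),
      error = function(e) NULL)
    if (!is.null(gfit)) {
      method <- paste0(method, "+gls_corGaus")
      tb <- summary(gfit)$tTable
      est <- c(tb["x", "Value"], tb["x", "Std.Error"], tb["x", "t-value"],
               tb["x", "p-value"])
      fit <- gfit
    }
  }
  structure(list(predictor = predictor, estimate = est[[1]], se = est[[2]],
                 t = est[[3]], p = est[[4]], method = method, moran = moran,
                 n = nrow(d), model = fit),
            class = "bii_gdp_fit")
}

#' @export
print.bii_gdp_fit <- function(x, ...) {
  cat(sprintf(
    "BII trend ~ %s (%s, n = %d): estimate = %.4g, se = %.3g, t = %.3g, p = %.3g\n",
    x$predictor, x$method, x$n, x$estimate, x$se, x$t, x$p))
  if (!is.null(x$moran)) {
    cat(sprintf("residual Moran's I = %.3g (p = %.3g)\n", x$moran$observed,
                x$moran$p.value))
  }
  invisible(x)
}
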