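#' Variable transformations used throughout the BII pipeline
#'
#' Human population density (HPD) is modelled on the \code{ln(x + 1)} scale,
#' road densities on the cube-root scale, compositional similarity on an
#' adjusted-logit scale, and geographic distance on the log scale after
#' division by the median sampling grain.
#'
#' @name bii-transforms
NULL

# adjustment used so that similarities of exactly 0 and 1 map to finite logits
.LOGIT_ADJ <- 0.01

#' Adjusted logit transform for compositional similarity
#'
#' Compresses \code{[0, 1]} linearly to \code{[adj, 1 - adj]} before taking the
#' logit, so that similarities of exactly 0 and 1 remain finite. The
#' compression is symmetric about 0.5 and exactly invertible by
#' [inv_logit_adjusted()].
#'
#' @param x numeric vector of similarities in \code{[0, 1]}. `NA` passes
#'   through.
#' @param adj compression adjustment, default 0.01.
#' @return numeric vector of adjusted logits.
#' @export
#' @examples
#' logit_adjusted(0.5) # 0
#' inv_logit_adjusted(logit_adjusted(0.25)) # 0.25
logit_adjusted <- function(x, adj = .LOGIT_ADJ) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop("logit_adjusted(): values outside [0, 1]: ",
         paste(utils::head(signif(x[bad], 4), 5L), collapse = ", "))
  }
  stats::qlogis(x * (1 - 2 * adj) + adj)
}

#' @rdname logit_adjusted
#' @param y numeric vector of adjusted logits.
#' @export
inv_logit_adjusted <- function(y, adj = .LOGIT_ADJ) {
  (stats::plogis(y) - adj) / (1 - 2 * adj)
}

#' Cube-root transform (used for road densities and Gower distance)
#' @param x non-negative numeric vector.
#' @return numeric vector.
#' @export
curt <- function(x) sign(x) * abs(x)^(1 / 3)

#' ln(x + 1) transform (used for human population density)
#' @param x non-negative numeric vector.
#' @return numeric vector.
#' @export
ln1p <- function(x) log1p(x)

#' Geographic distance scaled by the median sampling grain
#'
#' Distances are divided by the dataset-wide median maximum linear extent
#' (the sampling grain) before natural-log transformation, so a distance equal
#' to the median grain maps to 0. Co-located sites are floored at
#' \code{min_distance_m} before division because the log of zero is undefined.
#'
#' @param distance_m great-circle distance(s) in metres.
#' @param median_mle_m median maximum linear extent in metres (> 0).
#' @param min_distance_m floor applied to zero/near-zero distances, default 1 m.
#' @return ln(distance / median_mle).
#' @export
scaled_geo_distance <- function(distance_m, median_mle_m, min_distance_m = 1) {
  stopifnot(is.numeric(distance_m), length(median_mle_m) == 1L,
            is.finite(median_mle_m), median_mle_m > 0)
  log(pmax(distance_m, min_distance_m) / median_mle_m)
}

# standardisation helpers: parameters are estimated once on the modelling
# data and persisted in the fit artifact for projection-time reuse
standardize_fit <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1 # constant covariate: centre only
  list(mean = m, sd = s)
}

standardize_apply <- function(x, par) (x - par$mean) / par$sd
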