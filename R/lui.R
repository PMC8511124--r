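#' Land-use / use-intensity (LUI) vocabulary
#'
#' Raw assemblage records carry a land use from
#' \{primary, secondary, plantation, cropland, pasture, urban\} and a use
#' intensity from \{minimal, light, intense\}. Modelling and projection use a
#' single merged LUI factor with reference level \code{primary_minimal}:
#' plantation forest is folded into secondary vegetation (lightly- and
#' intensively-used plantation into intensively-used secondary; minimally-used
#' plantation into lightly-used secondary), primary vegetation keeps a
#' minimal vs light+intense split, secondary keeps all three intensities, and
#' cropland, pasture and urban are collapsed across intensities.
#'
#' @name bii-lui
NULL

.LAND_USES <- c("primary", "secondary", "plantation", "cropland", "pasture",
                "urban")
.INTENSITIES <- c("minimal", "light", "intense")

#' Merged LUI factor levels (reference level first)
#' @export
lui_levels <- function() {
  c("primary_minimal", "primary_light_intense",
    "secondary_minimal", "secondary_light", "secondary_intense",
    "cropland", "pasture", "urban")
}

#' Merge land use and use intensity into the modelling LUI class
#'
#' @param land_use character vector over
#'   \code{c("primary","secondary","plantation","cropland","pasture","urban")}.
#' @param use_intensity character vector over
#'   \code{c("minimal","light","intense")}.
#' @return factor with levels [lui_levels()].
#' @export
#' @examples
#' merge_plantation_lui("plantation", "minimal") # secondary_light
#' merge_plantation_lui("plantation", "intense") # secondary_intense
merge_plantation_lui <- function(land_use, use_intensity) {
  land_use <- as.character(land_use)
  use_intensity <- as.character(use_intensity)
  bad_lu <- setdiff(unique(land_use), .LAND_USES)
  if (length(bad_lu)) {
    stop("merge_plantation_lui(): unknown land use: ",
         paste(bad_lu, collapse = ", "))
  }
  bad_ui <- setdiff(unique(use_intensity), .INTENSITIES)
  if (length(bad_ui)) {
    stop("merge_plantation_lui(): unknown use intensity: ",
         paste(bad_ui, collapse = ", "))
  }
  if (length(land_use) != length(use_intensity)) {
    stop("merge_plantation_lui(): land_use and use_intensity lengths differ")
  }
  out <- character(length(land_use))
  plan <- land_use == "plantation"
  out[plan & use_intensity == "minimal"] <- "secondary_light"
  out[plan & use_intensity != "minimal"] <- "secondary_intense"
  prim <- land_use == "primary"
  out[prim & use_intensity == "minimal"] <- "primary_minimal"
  out[prim & use_intensity != "minimal"] <- "primary_light_intense"
  sec <- land_use == "secondary"
  out[sec] <- paste0("secondary_", use_intensity[sec])
  other <- land_use %in% c("cropland", "pasture", "urban")
  out[other] <- land_use[other]
  factor(out, levels = lui_levels())
}
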