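#' Read and write assemblage tables
#'
#' The assemblage CSV contract has one row per (study, site, species)
#' occurrence with columns study_id, site_id, block_id, longitude, latitude,
#' land_use, use_intensity, sampling_effort, max_linear_extent_m, metric,
#' species_id, abundance, elev, tmax_warm, tmin_cold, precip_wet, precip_dry.
#'
#' @param x assemblage data.frame.
#' @param path file path.
#' @return `read_assemblage_csv` returns the validated data.frame.
#' @export
write_assemblage_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assemblage_csv
#' @export
read_assemblage_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "site_id", "block_id", "longitude", "latitude",
            "land_use", "use_intensity", "sampling_effort",
            "max_linear_extent_m", "species_id", "abundance",
            "elev", "tmax_warm", "tmin_cold", "precip_wet", "precip_dry")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("read_assemblage_csv(): missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$abundance < 0)) stop("read_assemblage_csv(): negative abundances")
  if (any(d$sampling_effort <= 0)) {
    stop("read_assemblage_csv(): non-positive sampling effort")
  }
  invisible(merge_plantation_lui(d$land_use, d$use_intensity)) # vocab check
  d
}

#' Serialize a fitted component model to a JSON artifact
#'
#' The artifact is the projection contract: fixed-effect terms and estimates,
#' LUI factor levels, the fixed-effects formula, standardisation parameters,
#' covariate caps and auxiliary parameters (median sampling grain, Gower
#' ranges), plus the random-effect structure, variances and selection history
#' for the record. [read_bii_artifact()] restores an object that
#' [baseline_prediction()], [project_model()] and [predict.bii_fit()] accept
#' interchangeably with the original fit.
#'
#' @param fit a [bii_fit].
#' @param path JSON file path.
#' @return `write_bii_artifact` invisibly returns `path`; `read_bii_artifact`
#'   returns a `bii_fit`-classed artifact (without the lme4 model object).
#' @export
write_bii_artifact <- function(fit, path) {
  stopifnot(inherits(fit, "bii_fit"))
  vc <- as.data.frame(fit$varcor)
  art <- list(
    kind = fit$kind,
    lui_var = fit$lui_var,
    fixef = as.list(fit$fixef),
    fixed_formula = paste(deparse(stats::formula(fit$fixed_terms)),
                          collapse = " "),
    xlev = fit$xlev,
    standardize = fit$params$standardize,
    caps = fit$params$caps,
    median_mle = fit$params$median_mle,
    env_ranges = as.list(fit$params$env_ranges),
    sigma = fit$sigma,
    random_effects = vc[, c("grp", "var1", "vcov", "sdcor")],
    selection = list(
      random_slope = fit$selection$random_slope,
      dropped = fit$selection$dropped))
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_bii_artifact
#' @export
read_bii_artifact <- function(path) {
  art <- jsonlite::read_json(path, simplifyVector = TRUE)
  fe <- unlist(art$fixef)
  tt <- stats::delete.response(stats::terms(
    stats::as.formula(paste("~", sub("^.*~", "", art$fixed_formula)))))
  params <- list(standardize = lapply(art$standardize, as.list),
                 caps = lapply(art$caps, as.numeric),
                 median_mle = art$median_mle,
                 env_ranges = unlist(art$env_ranges))
  structure(list(kind = art$kind, fixef = fe,
                 coef_table = data.frame(term = names(fe),
                                         estimate = unname(fe)),
                 fixed_terms = tt,
                 xlev = lapply(art$xlev, as.character),
                 lui_var = art$lui_var,
                 params = params,
                 selection = art$selection,
                 sigma = art$sigma,
                 data = NULL, model = NULL, varcor = NULL),
            class = "bii_fit")
}

#' Export and import raster stacks as TIFF plus a JSON manifest
#'
#' Writes each layer as a single-band 32-bit float TIFF (values only) and the
#' grid geotransform, years and layer inventory as a JSON sidecar manifest.
#' Requires the optional `tiff` package.
#'
#' @param stack a [build_pressure_stack()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
export_stack_tiff <- function(stack, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("export_stack_tiff(): the 'tiff' package is not installed")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- list()
  wr <- function(m, name) {
    f <- file.path(dir, paste0(name, ".tif"))
    tiff::writeTIFF(m, f, bits.per.sample = 32, sampleformat = "float")
    layers[[name]] <<- basename(f)
  }
  for (y in stack$years) {
    key <- as.character(y)
    for (cls in names(stack$fractions[[key]])) {
      wr(stack$fractions[[key]][[cls]], sprintf("frac_%s_%s", cls, key))
    }
    wr(stack$ln1p_hpd[[key]], sprintf("ln1p_hpd_%s", key))
  }
  wr(stack$curt_road1, "curt_road1")
  wr(stack$curt_road50, "curt_road50")
  g <- stack$grid
  manifest <- list(grid = g[c("nrow", "ncol", "xmin", "xmax", "ymin", "ymax")],
                   years = stack$years, layers = layers)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
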