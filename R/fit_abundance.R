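.AB_FIXED <- paste(
  "sqrt_response ~ lui + ln1p_hpd_z + curt_road50_z + curt_road1_z +",
  "study_mean_ln1p_hpd_z + lui:ln1p_hpd_z + lui:curt_road50_z +",
  "lui:curt_road1_z")

#' Fit the mixed-effects model of square-root rescaled total abundance
#'
#' Gaussian linear mixed model of the square-root rescaled site total
#' abundance against the merged LUI factor, ln(1+HPD), cube-root road density
#' at the 1 km and 50 km scales, the two-way interactions of LUI with each
#' pressure, and the study-mean ln(1+HPD) sampling-bias control, with nested
#' random intercepts of spatial block within study. Optionally selects one
#' random slope by REML AIC ([select_random_slopes()]) and simplifies the
#' fixed effects by backward stepwise elimination under ML
#' ([backward_stepwise()]); the returned model is refitted with REML.
#'
#' @param abundance_data a `bii_model_data` from [prepare_abundance_data()].
#' @param random_slopes if `TRUE`, run AIC random-slope selection over
#'   `slope_candidates`.
#' @param slope_candidates standardised covariates considered for a random
#'   slope within study.
#' @param simplify if `TRUE`, backward stepwise simplification of the fixed
#'   effects (likelihood-ratio tests under ML at `alpha`).
#' @param alpha per-removal significance threshold for stepwise elimination.
#' @param protected terms never removed (the study-mean HPD control by
#'   default).
#' @param check_collinearity_warn if `TRUE`, GVIF-screen the main-effects
#'   design and warn above the threshold of 5.
#' @return a [bii_fit] of kind `"abundance"`.
#' @export
fit_abundance_model <- function(abundance_data,
                                random_slopes = TRUE,
                                slope_candidates = c("ln1p_hpd_z",
                                                     "curt_road50_z",
                                                     "curt_road1_z"),
                                simplify = TRUE,
                                alpha = 0.05,
                                protected = "study_mean_ln1p_hpd_z",
                                check_collinearity_warn = TRUE) {
  stopifnot(inherits(abundance_data, "bii_model_data"))
  d <- abundance_data$data
  if (length(unique(d$study_id)) < 2) {
    stop("fit_abundance_model(): need at least 2 studies")
  }
  d$lui <- droplevels(factor(d$lui, levels = lui_levels()))
  selection <- list()

  if (check_collinearity_warn) {
    gv <- try(check_collinearity(
      stats::reformulate(c("lui", "ln1p_hpd_z", "curt_road50_z",
                           "curt_road1_z", "study_mean_ln1p_hpd_z"),
                         response = "sqrt_response"), d), silent = TRUE)
    if (!inherits(gv, "try-error")) selection$gvif <- gv
  }

  random_base <- "(1 | study_id) + (1 | study_id:block_id)"
  fml <- stats::as.formula(paste(.AB_FIXED, "+", random_base))
  fit <- .fit_lmer(fml, d, REML = TRUE, step = "abundance base REML fit")

  if (random_slopes) {
    rs <- select_random_slopes(fit, slope_candidates, d)
    fit <- rs$fit
    selection$random_slope <- rs$slope
    selection$aic_table <- rs$aic_table
  }

  if (simplify) {
    st <- backward_stepwise(fit, d, protected = protected, alpha = alpha)
    selection$dropped <- st$dropped
    selection$stepwise_log <- st$log
    fit <- .fit_lmer(stats::formula(st$fit), d, REML = TRUE,
                     step = "abundance final REML refit")
  }

  .new_bii_fit("abundance", fit, d, abundance_data$params, "lui", selection)
}

#' Choose the random-effect structure by AIC among candidate random slopes
#'
#' Refits the REML model once per candidate with that covariate as a random
#' slope within study, and returns the structure with the lowest AIC among the
#' candidates that converged; differences of at most 2 AIC units from the
#' no-slope base are treated as ties resolved in favour of the simpler base
#' structure.
#'
#' @param base_fit converged REML `merMod` with random intercepts only.
#' @param candidates standardised covariate names to try as random slopes.
#' @param data the modelling data.
#' @return list with `fit` (chosen model), `slope` (covariate name or `NA`),
#'   and `aic_table`.
#' @export
select_random_slopes <- function(base_fit, candidates, data) {
  base_aic <- stats::AIC(base_fit)
  aic <- c(none = base_aic)
  fits <- list(none = base_fit)
  base_terms <- .random_terms(base_fit)
  for (v in candidates) {
    if (!v %in% colnames(data)) next
    rterms <- sub("^\\(1 \\| study_id\\)$", sprintf("(1 + %s | study_id)", v),
                  base_terms)
    if (identical(rterms, base_terms)) next # candidate identical to base
    fml <- stats::reformulate(
      c(attr(stats::terms(stats::formula(base_fit, fixed.only = TRUE)),
             "term.labels"), rterms))
    f <- tryCatch(.fit_lmer(.swap_response(fml, base_fit), data, REML = TRUE,
                            step = paste("random slope", v)),
                  error = function(e) NULL)
    if (!is.null(f)) {
      aic[v] <- stats::AIC(f)
      fits[[v]] <- f
    }
  }
  if (length(aic) == 1L) {
    warning("select_random_slopes(): no candidate converged; base retained")
    return(list(fit = base_fit, slope = NA_character_,
                aic_table = data.frame(structure = "none", AIC = base_aic)))
  }
  best <- names(aic)[which.min(aic)]
  # parsimony tie-break: keep the simpler base unless a slope wins by > 2
  if (best != "none" && base_aic - aic[best] <= 2) best <- "none"
  list(fit = fits[[best]],
       slope = if (best == "none") NA_character_ else best,
       aic_table = data.frame(structure = names(aic), AIC = unname(aic)))
}

# random-effect terms of a merMod as deparsed "(...)" strings
.random_terms <- function(model) {
  vapply(lme4::findbars(stats::formula(model)),
         function(b) paste0("(", deparse(b), ")"), character(1))
}

# rebuild a formula keeping the original response of a fitted model
.swap_response <- function(fml, model) {
  resp <- deparse(stats::formula(model)[[2]])
  rhs <- if (length(fml) == 3L) fml[[3]] else fml[[2]]
  stats::as.formula(paste(resp, "~", deparse1(rhs)), env = globalenv())
}

#' Backward stepwise simplification of the fixed effects under ML
#'
#' Iteratively removes the least-supported removable term: at each step every
#' term that is not protected and not marginal to a remaining interaction is
#' tested by a likelihood-ratio test of the ML fits, and the term with the
#' largest p-value above `alpha` is dropped. Stops when every removable term
#' is supported. The already-minimal model is returned unchanged.
#'
#' @param fit a `merMod` (refitted internally with ML).
#' @param data modelling data.
#' @param protected character vector of fixed terms never dropped.
#' @param alpha LRT significance threshold per removal.
#' @return list with `fit` (final ML model), `dropped` (terms removed in
#'   order) and `log` (data.frame of step, term, LR statistic, df, p).
#' @export
backward_stepwise <- function(fit, data, protected = character(),
                              alpha = 0.05) {
  ml <- .refit_ml(fit, data)
  rterms <- .random_terms(ml)
  dropped <- character()
  log_rows <- list()
  repeat {
    tl <- attr(stats::terms(stats::formula(ml, fixed.only = TRUE)),
               "term.labels")
    removable <- setdiff(tl, protected)
    # marginality: keep a term while a higher-order interaction contains it
    removable <- removable[vapply(removable, function(t) {
      parts <- strsplit(t, ":", fixed = TRUE)[[1]]
      !any(vapply(setdiff(tl, t), function(o) {
        op <- strsplit(o, ":", fixed = TRUE)[[1]]
        length(op) > length(parts) && all(parts %in% op)
      }, logical(1)))
    }, logical(1))]
    if (!length(removable)) break
    ll_full <- as.numeric(stats::logLik(ml))
    cand <- lapply(removable, function(t) {
      keep <- setdiff(tl, t)
      fml <- stats::reformulate(c(if (length(keep)) keep else "1", rterms),
                                response = deparse(stats::formula(ml)[[2]]))
      red <- tryCatch(.fit_lmer(fml, data, REML = FALSE,
                                step = paste("stepwise drop", t)),
                      error = function(e) NULL)
      if (is.null(red)) return(NULL)
      lr <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red))))
      df <- attr(stats::logLik(ml), "df") - attr(stats::logLik(red), "df")
      list(term = t, fit = red, lr = lr, df = max(df, 1L),
           p = stats::pchisq(lr, max(df, 1L), lower.tail = FALSE))
    })
    cand <- cand[!vapply(cand, is.null, logical(1))]
    if (!length(cand)) break
    ps <- vapply(cand, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = length(log_rows) + 1L, term = cand[[worst]]$term,
      lr = cand[[worst]]$lr, df = cand[[worst]]$df, p = ps[worst],
      dropped = ps[worst] > alpha)
    if (ps[worst] <= alpha) break
    dropped <- c(dropped, cand[[worst]]$term)
    ml <- cand[[worst]]$fit
  }
  list(fit = ml, dropped = dropped,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(step = integer(), term = character(), lr = numeric(),
                    df = integer(), p = numeric(), dropped = logical()))
}

.refit_ml <- function(fit, data) {
  if (!lme4::isREML(fit)) return(fit)
  .fit_lmer(stats::formula(fit), data, REML = FALSE, step = "ML refit")
}

#' Bootstrap confidence intervals for the fixed effects
#'
#' Parametric bootstrap (resampling from the fitted random-effect and residual
#' distributions, via [lme4::bootMer()]) by default; non-parametric resampling
#' of whole studies with replacement behind `type = "study"`. Percentile
#' intervals; a term is flagged significant when its interval excludes zero.
#'
#' @param fit a [bii_fit] or `merMod`.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed.
#' @param type `"parametric"` or `"study"`.
#' @param level confidence level, default 0.95.
#' @return data.frame of class `bii_bootstrap`: term, estimate, lower, upper,
#'   significant; attribute `n_failed` counts resamples that did not converge
#'   (parametric draws are redrawn internally by bootMer).
#' @export
bootstrap_coefficients <- function(fit, n_boot = 199, seed = 1,
                                   type = c("parametric", "study"),
                                   level = 0.95) {
  type <- match.arg(type)
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop("bootstrap_coefficients(): n_boot must be >= 1")
  }
  model <- if (inherits(fit, "bii_fit")) fit$model else fit
  data <- if (inherits(fit, "bii_fit")) fit$data else
    stats::model.frame(model)
  fe <- lme4::fixef(model)
  if (type == "parametric") {
    set.seed(seed)
    bs <- suppressWarnings(suppressMessages(
      lme4::bootMer(model, lme4::fixef, nsim = n_boot, type = "parametric",
                    use.u = FALSE)))
    draws <- bs$t
    n_failed <- sum(!stats::complete.cases(draws))
    draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  } else {
    set.seed(seed)
    studies <- unique(data$study_id)
    draws <- matrix(NA_real_, n_boot, length(fe),
                    dimnames = list(NULL, names(fe)))
    n_failed <- 0L
    b <- 1L
    while (b <= n_boot) {
      pick <- sample(studies, length(studies), replace = TRUE)
      dl <- lapply(seq_along(pick), function(k) {
        dd <- data[data$study_id == pick[k], , drop = FALSE]
        dd$study_id <- sprintf("bs%03d", k)
        dd
      })
      db <- do.call(rbind, dl)
      rf <- tryCatch(.fit_lmer(stats::formula(model), db,
                               REML = lme4::isREML(model),
                               step = "study bootstrap"),
                     error = function(e) NULL)
      if (is.null(rf)) { n_failed <- n_failed + 1L; next }
      fb <- lme4::fixef(rf)
      draws[b, names(fb)] <- fb
      b <- b + 1L
    }
    draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  }
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  out <- data.frame(term = names(fe), estimate = unname(fe),
                    lower = ci[names(fe), 1], upper = ci[names(fe), 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$lower > 0 | out$upper < 0
  attr(out, "n_failed") <- n_failed
  class(out) <- c("bii_bootstrap", "data.frame")
  out
}

#' Generalized variance inflation factors of a fixed-effects design
#'
#' GVIF screen of the main-effects design (via `car::vif` on an auxiliary
#' least-squares fit). A warning is raised when any term's
#' GVIF^(1/(2 df)) squared exceeds 5; a singular design is an error naming the
#' aliased columns.
#'
#' @param formula fixed-effects model formula (response required by `lm` but
#'   irrelevant to the result).
#' @param data modelling data.
#' @param threshold warning threshold on the squared df-scaled GVIF, default 5.
#' @return data.frame: term, gvif, df, gvif_scaled_sq.
#' @export
check_collinearity <- function(formula, data, threshold = 5) {
  lmfit <- stats::lm(formula, data = data)
  al <- stats::alias(lmfit)$Complete
  if (!is.null(al)) {
    stop("check_collinearity(): singular design; aliased columns: ",
         paste(rownames(al), collapse = ", "))
  }
  v <- car::vif(lmfit)
  if (is.matrix(v)) {
    out <- data.frame(term = rownames(v), gvif = v[, "GVIF"], df = v[, "Df"],
                      gvif_scaled_sq = v[, 3]^2, row.names = NULL)
  } else {
    out <- data.frame(term = names(v), gvif = unname(v), df = 1,
                      gvif_scaled_sq = unname(v), row.names = NULL)
  }
  high <- out$term[out$gvif_scaled_sq > threshold]
  if (length(high)) {
    warning("check_collinearity(): GVIF above ", threshold, " for: ",
            paste(high, collapse = ", "))
  }
  out
}
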