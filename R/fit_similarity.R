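.SIM_MAIN <- c("ln_scaled_geo_z", "curt_gower_z",
               "ln1p_hpd_j_z", "curt_road50_j_z", "curt_road1_j_z",
               "ln1p_hpd_diff_z", "curt_road50_diff_z", "curt_road1_diff_z",
               "study_mean_ln1p_hpd_z")

#' Fit the mixed-effects model of logit compositional similarity
#'
#' Gaussian linear mixed model of the adjusted-logit asymmetric Jaccard
#' similarity of each within-study pair against the land-use contrast (the
#' merged LUI class of the non-baseline site), ln-scaled geographic distance,
#' cube-root Gower environmental distance, each continuous pressure at site j
#' together with the baseline-minus-j difference, and the study-mean
#' ln(1+HPD) control, with a study random intercept. Interactions of the
#' contrast with the pressure-at-j covariates are included by default
#' (`interactions`); a random slope is optionally chosen by REML AIC among the
#' converged candidates.
#'
#' Because each site is compared with every other site in its study the pairs
#' are not independent, so naive likelihood-ratio tests are anticonservative;
#' use [permutation_lrt()] for term deletion and coefficient inference.
#' `simplify = TRUE` runs a permutation-based backward elimination (terms are
#' removed while their permuted-LRT p-value exceeds `alpha`).
#'
#' @param similarity_data a `bii_model_data` from [prepare_similarity_data()].
#' @param interactions continuous covariates interacted with the contrast
#'   factor.
#' @param random_slopes if `TRUE`, AIC selection of one random slope within
#'   study.
#' @param slope_candidates covariates considered for the random slope.
#' @param simplify if `TRUE`, permutation-based backward simplification.
#' @param alpha threshold for permutation-based removal tests.
#' @param n_perm permutations per removal test when `simplify = TRUE`.
#' @param seed seed for the simplification permutations.
#' @return a [bii_fit] of kind `"similarity"`.
#' @export
fit_similarity_model <- function(similarity_data,
                                 interactions = c("ln1p_hpd_j_z",
                                                  "curt_road50_j_z",
                                                  "curt_road1_j_z"),
                                 random_slopes = TRUE,
                                 slope_candidates = c("ln_scaled_geo_z",
                                                      "ln1p_hpd_j_z",
                                                      "curt_road50_j_z"),
                                 simplify = FALSE,
                                 alpha = 0.05,
                                 n_perm = 199,
                                 seed = 1) {
  stopifnot(inherits(similarity_data, "bii_model_data"))
  d <- similarity_data$data
  if (length(unique(d$study_id)) < 2) {
    stop("fit_similarity_model(): need pairs from at least 2 studies")
  }
  d$contrast <- droplevels(factor(d$contrast, levels = lui_levels()))
  terms <- c("contrast", .SIM_MAIN,
             if (length(interactions)) paste0("contrast:", interactions))
  fml <- stats::reformulate(c(terms, "(1 | study_id)"),
                            response = "logit_similarity")
  fit <- .fit_lmer(fml, d, REML = TRUE, step = "similarity base REML fit")
  selection <- list()

  if (random_slopes) {
    rs <- select_random_slopes(fit, slope_candidates, d)
    fit <- rs$fit
    selection$random_slope <- rs$slope
    selection$aic_table <- rs$aic_table
  }

  if (simplify) {
    sim <- .permutation_stepwise(fit, d, alpha = alpha, n_perm = n_perm,
                                 seed = seed)
    selection$dropped <- sim$dropped
    selection$permutation_log <- sim$log
    fit <- .fit_lmer(stats::formula(sim$fit), d, REML = TRUE,
                     step = "similarity final REML refit")
  }

  .new_bii_fit("similarity", fit, d, similarity_data$params, "contrast",
               selection)
}

#' Permute compositional-similarity responses within each study
#'
#' Shuffles the (transformed) similarity response uniformly within each study,
#' leaving all covariates untouched, so the permuted datasets preserve study
#' sizes and covariate structure but break the response-covariate link.
#' Single-pair studies are returned unchanged.
#'
#' @param pairs similarity-pair data.frame (needs `study_id`; the columns in
#'   `response` are permuted jointly).
#' @param seed integer seed.
#' @param response columns to permute; defaults to the transformed response
#'   plus the raw similarity for consistency.
#' @return data.frame with permuted response(s).
#' @export
permute_within_study <- function(pairs, seed,
                                 response = intersect(
                                   c("logit_similarity", "similarity"),
                                   colnames(pairs))) {
  set.seed(seed)
  idx <- seq_len(nrow(pairs))
  perm <- stats::ave(idx, pairs$study_id,
                     FUN = function(i) if (length(i) > 1) sample(i) else i)
  out <- pairs
  out[, response] <- pairs[perm, response, drop = FALSE]
  out
}

# deviance engine shared by permutation_lrt: fast closed-form path for
# single-random-intercept models, lme4::refit otherwise
.perm_engine <- function(model, data) {
  resp <- deparse(stats::formula(model)[[2]])
  if (.is_single_intercept(model)) {
    grp <- names(lme4::getME(model, "cnms"))
    X <- stats::model.matrix(
      stats::delete.response(stats::terms(stats::formula(model,
                                                         fixed.only = TRUE))),
      data)
    prep <- .fast_lmm_prepare(X, data[[grp]])
    function(y) .fast_lmm_deviance(prep, y)
  } else {
    ml <- if (lme4::isREML(model)) .refit_ml(model, data) else model
    function(y) {
      f <- suppressMessages(suppressWarnings(lme4::refit(ml, y)))
      as.numeric(-2 * stats::logLik(f))
    }
  }
}

#' Permutation likelihood-ratio test for non-independent similarity pairs
#'
#' Compares the observed ML likelihood ratio between a full model and a
#' reduced model nested within it against the distribution of likelihood
#' ratios obtained by refitting both models on datasets whose similarity
#' responses are shuffled within each study. The p-value is
#' (1 + #permuted >= observed) / (n_perm + 1).
#'
#' For models whose random structure is a single random intercept both the
#' observed and permuted deviances are evaluated with a closed-form profiled
#' ML likelihood (validated against lme4), which makes the default 1000
#' permutations affordable; any other structure falls back to `lme4::refit`.
#'
#' @param full,reduced fitted models ([bii_fit] or `merMod`); `reduced` must be
#'   nested in `full`.
#' @param pairs the similarity-pair modelling data both models were fitted to.
#' @param n_perm number of permutations (paper default 1000).
#' @param seed integer seed (mandatory).
#' @return object of class `bii_permutation`: list with `observed_lr`,
#'   `permuted` (length `n_perm`), `p`, `n_perm`, `seed`, `n_redrawn`.
#' @export
permutation_lrt <- function(full, reduced, pairs, n_perm = 1000, seed) {
  if (missing(seed)) stop("permutation_lrt(): seed is required")
  mf <- if (inherits(full, "bii_fit")) full$model else full
  mr <- if (inherits(reduced, "bii_fit")) reduced$model else reduced
  resp <- deparse(stats::formula(mf)[[2]])
  if (!identical(resp, deparse(stats::formula(mr)[[2]]))) {
    stop("permutation_lrt(): models have different responses")
  }
  dev_full <- .perm_engine(mf, pairs)
  dev_red <- .perm_engine(mr, pairs)
  y <- pairs[[resp]]
  obs <- max(0, dev_red(y) - dev_full(y))

  set.seed(seed)
  perm_lr <- numeric(n_perm)
  n_redrawn <- 0L
  idx <- seq_len(nrow(pairs))
  grp <- pairs$study_id
  k <- 1L
  while (k <= n_perm) {
    perm <- stats::ave(idx, grp,
                       FUN = function(i) if (length(i) > 1) sample(i) else i)
    yp <- y[perm]
    lr <- tryCatch(max(0, dev_red(yp) - dev_full(yp)), error = function(e) NA)
    if (is.na(lr)) { n_redrawn <- n_redrawn + 1L; next }
    perm_lr[k] <- lr
    k <- k + 1L
  }
  p <- (1 + sum(perm_lr >= obs - 1e-10)) / (n_perm + 1)
  structure(list(observed_lr = obs, permuted = perm_lr, p = p,
                 n_perm = n_perm, seed = seed, n_redrawn = n_redrawn),
            class = "bii_permutation")
}

#' @export
print.bii_permutation <- function(x, ...) {
  cat(sprintf("permutation LRT: observed LR = %.4g, p = %.4g (%d permutations)\n",
              x$observed_lr, x$p, x$n_perm))
  invisible(x)
}

#' Permutation significance of individual coefficients
#'
#' Compares each observed |t| statistic with the distribution of |t| obtained
#' by refitting the model on within-study permuted responses (the analogue of
#' the permuted likelihood-ratio test at the coefficient level).
#'
#' @param fit a [bii_fit] of kind `"similarity"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame: term, estimate, t, p_perm.
#' @export
permutation_coef_significance <- function(fit, n_perm = 1000, seed) {
  if (missing(seed)) stop("permutation_coef_significance(): seed is required")
  stopifnot(inherits(fit, "bii_fit"))
  obs_t <- abs(fit$coef_table$t)
  model <- fit$model
  set.seed(seed)
  exceed <- numeric(length(obs_t))
  idx <- seq_len(nrow(fit$data))
  y <- fit$data[[deparse(stats::formula(model)[[2]])]]
  for (k in seq_len(n_perm)) {
    perm <- stats::ave(idx, fit$data$study_id,
                       FUN = function(i) if (length(i) > 1) sample(i) else i)
    f <- suppressMessages(suppressWarnings(lme4::refit(model, y[perm])))
    tt <- lme4::fixef(f) / sqrt(diag(as.matrix(stats::vcov(f))))
    exceed <- exceed + (abs(tt) >= obs_t)
  }
  data.frame(term = fit$coef_table$term, estimate = fit$coef_table$estimate,
             t = fit$coef_table$t, p_perm = (1 + exceed) / (n_perm + 1),
             row.names = NULL)
}

# permutation-based backward elimination for the similarity model
.permutation_stepwise <- function(fit, data, alpha, n_perm, seed) {
  ml <- .refit_ml(fit, data)
  rterms <- .random_terms(ml)
  dropped <- character()
  log_rows <- list()
  step_seed <- seed
  repeat {
    tl <- attr(stats::terms(stats::formula(ml, fixed.only = TRUE)),
               "term.labels")
    removable <- tl[vapply(tl, function(t) {
      parts <- strsplit(t, ":", fixed = TRUE)[[1]]
      !any(vapply(setdiff(tl, t), function(o) {
        op <- strsplit(o, ":", fixed = TRUE)[[1]]
        length(op) > length(parts) && all(parts %in% op)
      }, logical(1)))
    }, logical(1))]
    if (!length(removable)) break
    best <- NULL
    for (t in removable) {
      keep <- setdiff(tl, t)
      fml <- stats::reformulate(c(if (length(keep)) keep else "1", rterms),
                                response = deparse(stats::formula(ml)[[2]]))
      red <- tryCatch(.fit_lmer(fml, data, REML = FALSE,
                                step = paste("permutation stepwise", t)),
                      error = function(e) NULL)
      if (is.null(red)) next
      pr <- permutation_lrt(ml, red, data, n_perm = n_perm, seed = step_seed)
      step_seed <- step_seed + 1L
      if (is.null(best) || pr$p > best$p) best <- list(term = t, fit = red,
                                                       p = pr$p,
                                                       lr = pr$observed_lr)
    }
    if (is.null(best)) break
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = length(log_rows) + 1L, term = best$term, lr = best$lr,
      p = best$p, dropped = best$p > alpha)
    if (best$p <= alpha) break
    dropped <- c(dropped, best$term)
    ml <- best$fit
  }
  list(fit = ml, dropped = dropped,
       log = if (length(log_rows)) do.call(rbind, log_rows) else NULL)
}
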