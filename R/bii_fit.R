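#' Fitted BII component model
#'
#' Both component models — square-root rescaled total abundance and
#' adjusted-logit compositional similarity — are Gaussian linear mixed-effects
#' models fitted with lme4 and wrapped, together with everything projection
#' needs (fixed-effect terms and estimates, factor levels, standardisation
#' parameters, covariate caps, selection history), in an object of class
#' `bii_fit`.
#'
#' @name bii_fit
NULL

# fit an lmer model with documented optimizer fallbacks; errors name the step
.fit_lmer <- function(formula, data, REML, step = "model fit") {
  force(formula); force(data); force(REML)
  opts <- c("nloptwrap", "bobyqa", "Nelder_Mead")
  last <- NULL
  for (op in opts) {
    ctrl <- lme4::lmerControl(optimizer = op, calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    fit <- tryCatch(
      suppressMessages(lme4::lmer(formula, data = data, REML = REML,
                                  control = ctrl)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      conv <- fit@optinfo$conv$lme4
      if (is.null(conv$code) || conv$code >= 0) {
        # embed the evaluated control and data in the call so that tools that
        # re-evaluate it (bootMer, update) do not depend on this frame
        fit@call$control <- ctrl
        fit@call$data <- data
        return(fit)
      }
    }
    last <- fit
  }
  stop("lmer did not converge during ", step, ": ",
       if (inherits(last, "error")) conditionMessage(last) else "all optimizers failed")
}

.new_bii_fit <- function(kind, model, data, params, lui_var, selection) {
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  tt <- stats::delete.response(stats::terms(stats::formula(model,
                                                           fixed.only = TRUE)))
  structure(list(
    kind = kind,
    model = model,
    fixef = fe,
    coef_table = data.frame(term = names(fe), estimate = unname(fe),
                            se = unname(se), t = unname(fe / se),
                            stringsAsFactors = FALSE),
    fixed_terms = tt,
    xlev = stats::setNames(list(levels(droplevels(data[[lui_var]]))), lui_var),
    lui_var = lui_var,
    params = params,
    selection = selection,
    data = data,
    sigma = stats::sigma(model),
    varcor = lme4::VarCorr(model)),
    class = "bii_fit")
}

# design matrix for the fixed effects of a fit/artifact, aligned to fixef
.fixed_design <- function(object, newdata) {
  lv <- object$xlev[[object$lui_var]]
  val <- as.character(newdata[[object$lui_var]])
  unknown <- setdiff(unique(val), lv)
  if (length(unknown)) {
    stop("LUI class(es) absent from the fitted model: ",
         paste(unknown, collapse = ", "))
  }
  newdata[[object$lui_var]] <- factor(val, levels = lv)
  xuse <- object$xlev[intersect(names(object$xlev),
                                all.vars(object$fixed_terms))]
  X <- stats::model.matrix(object$fixed_terms, newdata, xlev = xuse)
  miss <- setdiff(names(object$fixef), colnames(X))
  if (length(miss)) stop("design is missing fitted columns: ",
                         paste(miss, collapse = ", "))
  X[, names(object$fixef), drop = FALSE]
}

#' @export
print.bii_fit <- function(x, ...) {
  cat(sprintf("bii_fit (%s model): %d fixed-effect terms, %d rows\n",
              x$kind, length(x$fixef), nrow(x$data)))
  cat("random effects:\n")
  print(x$varcor, comp = "Std.Dev.")
  if (!is.null(x$selection$random_slope)) {
    cat("random slope selected:", x$selection$random_slope, "\n")
  }
  if (length(x$selection$dropped)) {
    cat("terms dropped by stepwise simplification:",
        paste(x$selection$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.bii_fit <- function(object, ...) {
  out <- list(kind = object$kind, coef = object$coef_table,
              varcor = object$varcor, sigma = object$sigma,
              n = nrow(object$data), selection = object$selection)
  class(out) <- "summary.bii_fit"
  out
}

#' @export
print.summary.bii_fit <- function(x, ...) {
  cat(sprintf("BII %s model (%d rows)\nFixed effects:\n", x$kind, x$n))
  print(x$coef, digits = 4, row.names = FALSE)
  cat("\nRandom effects:\n")
  print(x$varcor, comp = "Std.Dev.")
  invisible(x)
}

#' @export
coef.bii_fit <- function(object, ...) object$fixef

#' Fixed-effect predictions from a BII component model
#'
#' Predicts with random effects set to zero, exactly reproducing the
#' projection-time linear predictor. `newdata` must carry the merged LUI
#' factor column and the standardised covariate columns used in the model
#' (`*_z`); rows of the training data work directly.
#'
#' @param object a `bii_fit`.
#' @param newdata data.frame of prediction rows; defaults to the training data.
#' @param type `"link"` for the linear predictor, `"response"` for the natural
#'   scale (squared for abundance with negative predictors floored at zero;
#'   inverse adjusted logit for similarity).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.bii_fit <- function(object, newdata = NULL,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  eta <- drop(.fixed_design(object, newdata) %*% object$fixef)
  if (type == "link") return(eta)
  if (object$kind == "abundance") pmax(eta, 0)^2 else inv_logit_adjusted(eta)
}
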