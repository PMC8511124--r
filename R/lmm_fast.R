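# Profiled ML deviance of a Gaussian LMM with a single random intercept.
#
# For y = X beta + Z u + e with one grouping factor, V = sigma^2 (I + lambda
# Z Z') and lambda = var_u / var_e. Profiling beta and sigma^2 leaves a 1-D
# problem in lambda; GLS for a given lambda reduces to quasi-demeaning each
# group by w_g = 1 - sqrt(1 / (1 + n_g lambda)). The deviance is
#   n log(2 pi RSS(lambda) / n) + n + sum_g log(1 + n_g lambda).
# This is mathematically the ML deviance lme4 computes and is validated
# against lme4 in the test suite; the permutation engine uses it because a
# within-study permutation test refits the model hundreds of thousands of
# times.

.fast_lmm_prepare <- function(X, group) {
  group <- as.factor(group)
  gi <- as.integer(group)
  ng <- tabulate(gi)
  list(X = X, gi = gi, ng = ng, n = nrow(X),
       Xbar = rowsum(X, gi) / ng)
}

.fast_lmm_dev_at <- function(prep, y, ybar, lambda) {
  w <- 1 - sqrt(1 / (1 + prep$ng * lambda))
  wi <- w[prep$gi]
  yt <- y - wi * ybar[prep$gi]
  Xt <- prep$X - wi * prep$Xbar[prep$gi, , drop = FALSE]
  rss <- sum(stats::.lm.fit(Xt, yt)$residuals^2)
  prep$n * log(2 * pi * rss / prep$n) + prep$n +
    sum(log(1 + prep$ng * lambda))
}

.fast_lmm_deviance <- function(prep, y) {
  ybar <- as.numeric(rowsum(y, prep$gi) / prep$ng)
  f <- function(ll) .fast_lmm_dev_at(prep, y, ybar, exp(ll))
  opt <- stats::optimize(f, interval = c(-12, 12), tol = 1e-7)
  dev0 <- .fast_lmm_dev_at(prep, y, ybar, 0) # boundary: no group variance
  min(opt$objective, dev0)
}

# TRUE when a merMod has exactly one random term: an intercept for one factor
.is_single_intercept <- function(model) {
  cn <- lme4::getME(model, "cnms")
  length(cn) == 1L && identical(unname(cn[[1]]), "(Intercept)")
}
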