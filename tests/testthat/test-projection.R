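# hand-built artifact-style fit with known coefficients, for closed-form checks
hand_fit <- function(kind, fixef, lui_var = if (kind == "abundance") "lui"
                     else "contrast") {
  covs <- if (kind == "abundance") biintact:::.AB_COVARS else
    biintact:::.SIM_COVARS
  std <- lapply(stats::setNames(covs, covs), function(v)
    list(mean = 0, sd = 1))
  capvars <- grep("geo|gower|study_mean", covs, value = TRUE, invert = TRUE)
  caps <- lapply(stats::setNames(capvars, capvars), function(v) c(-10, 10))
  structure(list(
    kind = kind, fixef = fixef,
    fixed_terms = stats::delete.response(stats::terms(stats::reformulate(
      names(fixef)[-1], response = NULL))),
    xlev = stats::setNames(list(lui_levels()), lui_var),
    lui_var = lui_var,
    params = list(standardize = std, caps = caps)), class = "bii_fit")
}

test_that("baseline predictions follow closed forms", {
  # intercept-only abundance model: baseline = beta0^2
  f <- hand_fit("abundance", c("(Intercept)" = 0.9, ln1p_hpd_z = 0,
                               curt_road50_z = 0, curt_road1_z = 0,
                               study_mean_ln1p_hpd_z = 0))
  expect_equal(baseline_prediction(f), 0.81)
  # hand-built 3-coefficient fit: manual linear-predictor arithmetic.
  # standardisation (mean 1, sd 2) sends the raw zero pressure to z = -0.5
  f2 <- hand_fit("abundance", c("(Intercept)" = 0.8, ln1p_hpd_z = 0.1,
                                curt_road50_z = 0, curt_road1_z = 0,
                                study_mean_ln1p_hpd_z = 0.3))
  f2$params$standardize$ln1p_hpd <- list(mean = 1, sd = 2)
  expect_equal(baseline_prediction(f2), (0.8 + 0.1 * (-0.5) + 0.3 * 0)^2)
  # similarity baseline: geographic distance at the median grain contributes
  # its standardised zero
  f3 <- hand_fit("similarity", stats::setNames(
    c(1.2, -0.4, rep(0, 8)),
    c("(Intercept)", "ln_scaled_geo_z",
      paste0(biintact:::.SIM_COVARS[-1], "_z"))))
  f3$params$standardize$ln_scaled_geo <- list(mean = 0.5, sd = 1)
  expect_equal(baseline_prediction(f3),
               inv_logit_adjusted(1.2 - 0.4 * (0 - 0.5)))
  f4 <- f3; f4$params$standardize <- NULL
  expect_error(baseline_prediction(f4), "standardisation")
})

test_that("a pristine cell and a pristine world sit at BII = 1 exactly", {
  fw <- fitted_world()
  st0 <- pristine_stack()
  for (y in c(2001, 2012)) {
    ra <- project_model(fw$fit_ab, st0, y)
    rs <- project_model(fw$fit_sim, st0, y)
    b <- compute_bii(ra, rs, st0$grid, y)
    expect_true(all(b$bii == 1))
  }
  agg <- aggregate_region(compute_bii(project_model(fw$fit_ab, st0, 2005),
                                      project_model(fw$fit_sim, st0, 2005),
                                      st0$grid, 2005),
                          matrix("R01", st0$grid$nrow, st0$grid$ncol))
  expect_equal(agg$mean_bii, 1)
})

test_that("fraction weighting combines class predictions on the natural scale", {
  fw <- fitted_world()
  st0 <- pristine_stack(grid_shape = c(2, 2))
  # make one cell a 50/50 mix of primary_minimal and cropland, zero pressures
  y <- "2001"
  st0$fractions[[y]]$primary_minimal[1, 1] <- 0.5
  st0$fractions[[y]]$cropland[1, 1] <- 0.5
  r <- project_model(fw$fit_ab, st0, 2001)
  # class-level relative predictions at zero pressure
  base <- baseline_prediction(fw$fit_ab)
  nd <- biintact:::.projection_newdata(fw$fit_ab, st0, 2001, "cropland")
  eta <- drop(biintact:::.fixed_design(fw$fit_ab, nd[1, , drop = FALSE]) %*%
                fw$fit_ab$fixef)
  crop_rel <- unname(pmax(eta, 0)^2 / base)
  expect_equal(r[1, 1], (1 + crop_rel) / 2, tolerance = 1e-12)
  expect_equal(r[2, 2], 1)
})

test_that("vectorised projection equals a per-cell per-class loop", {
  fw <- fitted_world()
  st <- fw$stack
  for (fit in list(fw$fit_ab, fw$fit_sim)) {
    got <- project_model(fit, st, 2012)
    base <- baseline_prediction(fit)
    want <- matrix(NA_real_, st$grid$nrow, st$grid$ncol)
    for (i in seq_len(st$grid$nrow)) {
      for (j in seq_len(st$grid$ncol)) {
        acc <- 0; tot <- 0
        for (cls in names(st$fractions[["2012"]])) {
          w <- st$fractions[["2012"]][[cls]][i, j]
          tot <- tot + w
          if (w == 0) next
          cell_stack <- list(
            grid = NULL,
            ln1p_hpd = stats::setNames(
              list(matrix(st$ln1p_hpd[["2012"]][i, j])), "2012"),
            curt_road50 = matrix(st$curt_road50[i, j]),
            curt_road1 = matrix(st$curt_road1[i, j]))
          nd <- biintact:::.projection_newdata(fit, cell_stack, 2012, cls)
          eta <- drop(biintact:::.fixed_design(fit, nd) %*% fit$fixef)
          acc <- acc + w * biintact:::.natural_scale(fit$kind, eta)
        }
        want[i, j] <- if (tot > 0) acc / tot / base else NA_real_
      }
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("BII composition is a commutative cellwise product with guards", {
  g <- bii_grid(3, 3)
  a <- matrix(stats::runif(9), 3, 3)
  s <- matrix(stats::runif(9), 3, 3)
  b <- compute_bii(a, s, g, 2005)
  expect_equal(b$bii, a * s)
  expect_equal(b$bii, compute_bii(s, a, g, 2005)$bii)
  expect_equal(compute_bii(matrix(1, 3, 3), matrix(1, 3, 3), g, 2005)$bii[2, 2],
               1)
  expect_equal(compute_bii(matrix(0.8, 3, 3), matrix(0.5, 3, 3), g,
                           2005)$bii[1, 1], 0.4)
  expect_error(compute_bii(a, matrix(1, 2, 2), g, 2005), "mismatch")
})

test_that("projection rejects LUI classes the model has not seen", {
  fw <- fitted_world()
  fit <- fw$fit_ab
  fit$xlev$lui <- setdiff(fit$xlev$lui, "urban")
  expect_error(project_model(fit, fw$stack, 2001), "urban")
})

test_that("projection respects the training covariate hull and monotonicity", {
  fw <- fitted_world()
  st <- fw$stack
  caps <- fw$fit_ab$params$caps
  # capped inputs never leave the training range
  capped <- cap_to_model_range(st$ln1p_hpd[["2001"]], caps, "ln1p_hpd")
  expect_true(all(capped >= caps$ln1p_hpd[1] & capped <= caps$ln1p_hpd[2]))
  # BII decreases as cropland replaces primary when both fitted cropland
  # responses are negative (checked on this synthetic fit)
  ct_ab <- coef(fw$fit_ab)
  ct_sim <- coef(fw$fit_sim)
  expect_lt(ct_ab[["luicropland"]], 0)
  expect_lt(ct_sim[["contrastcropland"]], 0)
  st2 <- pristine_stack(grid_shape = c(1, 3))
  y <- "2001"
  shares <- c(0, 0.4, 0.8)
  for (k in 1:3) {
    st2$fractions[[y]]$primary_minimal[1, k] <- 1 - shares[k]
    st2$fractions[[y]]$cropland[1, k] <- shares[k]
  }
  b <- compute_bii(project_model(fw$fit_ab, st2, 2001),
                   project_model(fw$fit_sim, st2, 2001), st2$grid, 2001)
  expect_true(all(diff(as.vector(b$bii[1, ])) < 0))
})

test_that("model artifacts round-trip through JSON for projection", {
  fw <- fitted_world()
  tf <- tempfile(fileext = ".json")
  write_bii_artifact(fw$fit_ab, tf)
  art <- read_bii_artifact(tf)
  expect_equal(art$fixef, fw$fit_ab$fixef, tolerance = 1e-12)
  expect_equal(baseline_prediction(art), baseline_prediction(fw$fit_ab),
               tolerance = 1e-10)
  expect_equal(project_model(art, fw$stack, 2001),
               project_model(fw$fit_ab, fw$stack, 2001), tolerance = 1e-10)
  ts <- tempfile(fileext = ".json")
  write_bii_artifact(fw$fit_sim, ts)
  art_s <- read_bii_artifact(ts)
  expect_equal(project_model(art_s, fw$stack, 2012),
               project_model(fw$fit_sim, fw$stack, 2012), tolerance = 1e-10)
})
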