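test_that("population interpolation follows the 0.8/0.2 rule on the ln scale", {
  set.seed(3)
  snaps <- lapply(c(2000, 2005, 2010, 2015), function(y)
    matrix(stats::rlnorm(12, 2, 1), 3, 4))
  names(snaps) <- c("2000", "2005", "2010", "2015")
  got <- interpolate_hpd(snaps, 2006)
  want <- 0.8 * log1p(snaps[["2005"]]) + 0.2 * log1p(snaps[["2010"]])
  expect_equal(got, want, tolerance = 1e-14)
  # snapshots exact
  for (y in c(2000, 2005, 2010, 2015)) {
    expect_equal(interpolate_hpd(snaps, y), log1p(snaps[[as.character(y)]]))
  }
  # constant snapshots give constant output
  const <- lapply(snaps, function(m) matrix(5, 3, 4))
  expect_equal(interpolate_hpd(const, 2007), matrix(log1p(5), 3, 4))
  # monotone between ordered endpoints
  vals <- sapply(2005:2010, function(y) interpolate_hpd(snaps, y)[2, 2])
  if (snaps[["2005"]][2, 2] < snaps[["2010"]][2, 2]) {
    expect_true(all(diff(vals) >= 0))
  } else {
    expect_true(all(diff(vals) <= 0))
  }
  expect_error(interpolate_hpd(snaps, 1999), "outside")
  expect_error(interpolate_hpd(snaps, 2016), "outside")
})

test_that("road density matches a brute-force sampling oracle", {
  g <- bii_grid(5, 5)
  expect_warning(z <- road_density(data.frame(x0 = numeric(), y0 = numeric(),
                                              x1 = numeric(), y1 = numeric()),
                                   g, radius_km = 50), "no road")
  expect_true(all(z == 0))

  segs <- data.frame(x0 = 0.3, y0 = -1.2, x1 = 4.1, y1 = 2.2)
  r <- 60
  got <- road_density(segs, g, radius_km = r)
  # oracle: dense point sampling along the segment
  k <- 111.32
  npts <- 20000
  t <- (seq_len(npts) - 0.5) / npts
  px <- (segs$x0 + t * (segs$x1 - segs$x0)) * k
  py <- (segs$y0 + t * (segs$y1 - segs$y0)) * k
  seg_len <- sqrt(((segs$x1 - segs$x0) * k)^2 + ((segs$y1 - segs$y0) * k)^2)
  step <- seg_len / npts
  for (i in c(1, 3, 5)) {
    for (j in c(1, 3, 5)) {
      cx <- g$lon[j] * k; cy <- g$lat[i] * k
      inside <- (px - cx)^2 + (py - cy)^2 <= r^2
      want <- sum(inside) * step / (pi * r^2)
      expect_equal(got[i, j], want, tolerance = 1e-3)
    }
  }
  # locality: a tiny radius only sees roads passing right by the cell centre
  tiny <- road_density(segs, g, radius_km = 0.5)
  far <- sqrt((g$lon[1] * k - px)^2 + (g$lat[1] * k - py)^2)
  expect_true(min(far) > 0.5)
  expect_equal(tiny[1, 1], 0)
})

test_that("forest harmonization reproduces the stated rules exactly", {
  # rule 1: predicted primary above observed forest
  h <- harmonize_with_forest(0.6, 0.1, 0.1, 0.1, 0.1, 0.4)
  expect_equal(h$primary, 0.4)
  expect_equal(h$secondary, 0.15)
  expect_equal(h$cropland, 0.15)
  expect_equal(h$primary + h$secondary + h$cropland + h$pasture + h$urban, 1)
  # rule 2: primary + secondary below observed forest
  h2 <- harmonize_with_forest(0.18, 0.12, 0.3, 0.3, 0.1, 0.5)
  expect_equal(h2$primary, 0.18 * 5 / 3)
  expect_equal(h2$secondary, 0.12 * 5 / 3)
  expect_equal(h2$cropland, 0.3 * 5 / 7)
  expect_equal(h2$primary + h2$secondary + h2$cropland + h2$pasture + h2$urban,
               1)
  # no-op region
  h3 <- harmonize_with_forest(0.4, 0.2, 0.2, 0.1, 0.1, 0.4)
  expect_equal(h3, list(primary = 0.4, secondary = 0.2, cropland = 0.2,
                        pasture = 0.1, urban = 0.1), ignore_attr = TRUE)
  # degenerate: rule 1 with all non-primary fractions zero
  h4 <- harmonize_with_forest(0.9, 0, 0, 0, 0, 0.5)
  expect_equal(h4$primary, 0.5)
  expect_equal(h4$secondary, 0.4)
  expect_equal(attr(h4, "n_excess_to_secondary"), 1L)
  expect_error(harmonize_with_forest(-0.1, 0.2, 0.2, 0.2, 0.2, 0.5),
               "negative")
  expect_error(harmonize_with_forest(0.1, 0.2, 0.2, 0.2, 0.2, 1.5), "forest")
})

test_that("harmonization fuzzing preserves totals and never goes negative", {
  set.seed(10)
  n <- 5000
  raw <- matrix(stats::rexp(5 * n), n, 5)
  fr <- raw / rowSums(raw) * stats::runif(n) # five-class total <= 1
  F <- stats::runif(n)
  h <- harmonize_with_forest(fr[, 1], fr[, 2], fr[, 3], fr[, 4], fr[, 5], F)
  out <- cbind(h$primary, h$secondary, h$cropland, h$pasture, h$urban)
  expect_true(all(out >= -1e-12))
  expect_true(all(abs(rowSums(out) - rowSums(fr)) < 1e-9))
  rule <- attr(h, "rule")
  Fe <- pmin(F, rowSums(fr))
  # whichever rule fired, its constraint holds afterwards
  expect_true(all(abs(out[rule == 1, 1] - Fe[rule == 1]) < 1e-12))
  expect_true(all(out[rule == 2, 1] + out[rule == 2, 2] - Fe[rule == 2] >
                    -1e-9))
  none <- rule == 0
  expect_true(all(abs(out[none, ] - fr[none, ]) < 1e-12))
})

test_that("intensity allocation conserves fractions and responds to HPD", {
  g <- matrix(log1p(stats::rlnorm(20, 2, 1)), 4, 5)
  fr <- list(primary = matrix(0.4, 4, 5), secondary = matrix(0.3, 4, 5),
             cropland = matrix(0.2, 4, 5), pasture = matrix(0.05, 4, 5),
             urban = matrix(0.05, 4, 5))
  out <- allocate_intensity(fr, g)
  expect_setequal(names(out), lui_levels())
  # per-class shares sum to the input fraction
  expect_true(all(abs(out$primary_minimal + out$primary_light_intense -
                        fr$primary) < 1e-12))
  expect_true(all(abs(out$secondary_minimal + out$secondary_light +
                        out$secondary_intense - fr$secondary) < 1e-12))
  expect_true(all(abs(Reduce(`+`, out) - Reduce(`+`, fr)) < 1e-12))
  # forced shares: everything minimal
  ic <- default_intensity_coefs()
  ic$slope <- 0
  ic$intercept <- ifelse(ic$intensity == "minimal", 50, -50)
  out2 <- allocate_intensity(fr, g, coefs = ic)
  expect_equal(out2$primary_minimal, fr$primary, tolerance = 1e-12)
  expect_true(all(out2$primary_light_intense < 1e-12))
  # monotone: intense share of the default table increases with HPD
  hseq <- matrix(seq(0, 8, length.out = 20), 4, 5)
  out3 <- allocate_intensity(fr, hseq)
  intense_share <- out3$secondary_intense / fr$secondary
  expect_true(all(diff(as.vector(intense_share)[order(as.vector(hseq))]) > 0))
  # malformed tables rejected with the missing entries named
  expect_error(allocate_intensity(fr, g, coefs = ic[ic$land_use != "urban", ]),
               "urban")
})

test_that("capping clips to the stored range and preserves order", {
  caps <- list(v = c(-1, 2))
  x <- matrix(seq(-3, 4, length.out = 12), 3, 4)
  y <- cap_to_model_range(x, caps, "v")
  expect_true(all(y >= -1 & y <= 2))
  expect_equal(y[x >= -1 & x <= 2], x[x >= -1 & x <= 2])
  expect_true(all(diff(as.vector(y)[order(as.vector(x))] ) >= 0))
  expect_error(cap_to_model_range(x, caps, "w"), "no caps")
})

test_that("the stack builder is idempotent", {
  fw <- fitted_world()
  s1 <- build_pressure_stack(fw$pressure_world)
  s2 <- build_pressure_stack(fw$pressure_world)
  expect_identical(s1, s2)
  # merged fractions conserve the land total for every year
  for (y in c("2001", "2012")) {
    tot_lu <- Reduce(`+`, fw$pressure_world$lu[[y]])
    tot_m <- Reduce(`+`, s1$fractions[[y]])
    expect_equal(tot_m, tot_lu, tolerance = 1e-12)
  }
})
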