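test_that("plantation classes merge into secondary and vocab errors are named", {
  expect_equal(as.character(merge_plantation_lui("plantation", "minimal")),
               "secondary_light")
  expect_equal(as.character(merge_plantation_lui("plantation", "light")),
               "secondary_intense")
  expect_equal(as.character(merge_plantation_lui("plantation", "intense")),
               "secondary_intense")
  expect_equal(as.character(merge_plantation_lui("primary", "minimal")),
               "primary_minimal")
  expect_equal(as.character(merge_plantation_lui("primary", "intense")),
               "primary_light_intense")
  expect_equal(as.character(merge_plantation_lui("secondary", "minimal")),
               "secondary_minimal")
  expect_equal(
    as.character(merge_plantation_lui(c("cropland", "pasture", "urban"),
                                      c("minimal", "light", "intense"))),
    c("cropland", "pasture", "urban"))
  expect_error(merge_plantation_lui("swamp", "minimal"), "swamp")
  expect_error(merge_plantation_lui("primary", "extreme"), "extreme")
})

test_that("effort correction and max rescaling follow the two-pass oracle", {
  rec <- data.frame(study_id = "s", site_id = rep(c("a", "b", "c"), 2),
                    sampling_effort = 1,
                    abundance = c(1, 2, 4, 1, 2, 4), metric = "count")
  out <- effort_correct_and_rescale(rec)
  expect_equal(out$rescaled[match(c("a", "b", "c"), out$site_id)],
               c(0.25, 0.5, 1.0))

  rec2 <- data.frame(study_id = "s", site_id = c("a", "a", "b"),
                     sampling_effort = c(2, 2, 1),
                     abundance = c(6, 4, 5), metric = "count")
  out2 <- effort_correct_and_rescale(rec2)
  expect_equal(out2$rescaled, c(1, 1))

  # effort-insensitive metric: no division even when effort varies
  rec3 <- rec2; rec3$metric <- "density"
  out3 <- effort_correct_and_rescale(rec3)
  expect_equal(out3$total, c(10, 5))

  set.seed(1)
  for (k in 1:20) {
    ns <- sample(3:8, 1)
    rec <- data.frame(
      study_id = "s",
      site_id = rep(sprintf("s%02d", seq_len(ns)), each = 4),
      sampling_effort = rep(stats::runif(ns, 0.5, 3), each = 4),
      abundance = stats::rlnorm(ns * 4), metric = "count")
    out <- effort_correct_and_rescale(rec)
    # independent two-pass recomputation: sum, divide, max-scale
    tot <- sapply(split(rec, rec$site_id), function(d)
      sum(d$abundance) / d$sampling_effort[1])
    expect_equal(out$rescaled[match(names(tot), out$site_id)],
                 unname(tot / max(tot)), tolerance = 1e-12)
  }
  expect_warning(
    effort_correct_and_rescale(data.frame(study_id = "s", site_id = c("a", "b"),
                                          sampling_effort = 1,
                                          abundance = c(0, 0),
                                          metric = "count")),
    "zero")
})

test_that("asymmetric Jaccard matches its definition, boundaries and oracle", {
  expect_equal(asymmetric_jaccard(c(A = 1, B = 2), c(A = 3, C = 1)), 0.75)
  expect_equal(asymmetric_jaccard(c(A = 1, B = 1), c(A = 2, B = 5)), 1.0)
  expect_equal(asymmetric_jaccard(c(A = 1), c(B = 2, C = 3)), 0.0)
  expect_true(is.na(asymmetric_jaccard(c(A = 1), c(A = 0, B = 0))))
  # self-similarity of any non-empty site is 1
  set.seed(2)
  for (k in 1:10) {
    x <- random_counts()
    if (sum(x) == 0) next
    expect_equal(asymmetric_jaccard(x, x), 1)
  }
  # genuinely asymmetric
  i <- c(A = 5, B = 5)
  j <- c(A = 1, C = 9)
  expect_equal(asymmetric_jaccard(i, j), 0.1)
  expect_equal(asymmetric_jaccard(j, i), 0.5)
  set.seed(3)
  for (k in 1:200) {
    ci <- random_counts(); cj <- random_counts()
    got <- asymmetric_jaccard(ci, cj)
    want <- jaccard_oracle(ci, cj)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(asymmetric_jaccard(c(A = -1), c(A = 1)), "negative")
})

test_that("Gower dissimilarity hits its boundary cases and formula", {
  r <- c(a = 2, b = 10, c = 0)
  expect_equal(gower_env_distance(c(1, 5, 3), c(1, 5, 3), r), 0)
  expect_equal(gower_env_distance(c(0, 0, 1), c(2, 10, 1), r), 2 / 3)
  set.seed(4)
  for (k in 1:20) {
    x <- stats::rnorm(5); y <- stats::rnorm(5); rg <- stats::runif(5, 0.5, 2)
    expect_equal(gower_env_distance(x, y, rg), mean(abs(x - y) / rg))
  }
  expect_true(is.na(gower_env_distance(c(1, NA), c(1, 2), c(1, 1))))
})

test_that("scaled geographic distance is zero at the median grain", {
  expect_equal(scaled_geo_distance(150, 150), 0)
  expect_equal(scaled_geo_distance(exp(1) * 150, 150), 1)
  # co-located sites floored before division
  expect_equal(scaled_geo_distance(0, 100), log(1 / 100))
  expect_error(scaled_geo_distance(10, -1))
})

test_that("adjusted logit is symmetric, invertible and finite at the bounds", {
  expect_equal(logit_adjusted(0.5), 0)
  for (x in c(0, 0.25, 1)) {
    expect_equal(inv_logit_adjusted(logit_adjusted(x)), x, tolerance = 1e-12)
  }
  expect_equal(logit_adjusted(0), log(0.01 / 0.99))
  expect_equal(logit_adjusted(1), log(0.99 / 0.01))
  expect_error(logit_adjusted(1.2), "outside")
  expect_error(logit_adjusted(-0.1), "outside")
})

test_that("pair construction follows the baseline pairing rule", {
  mk_rec <- function(lui, effort = rep(1, length(lui))) {
    n <- length(lui)
    base <- lui == "primary_minimal"
    data.frame(study_id = "s", site_id = sprintf("x%d", seq_len(n)),
               block_id = "b1", longitude = seq_len(n) * 0.01, latitude = 0,
               land_use = ifelse(base, "primary", "cropland"),
               use_intensity = ifelse(base, "minimal", "light"),
               sampling_effort = effort,
               max_linear_extent_m = 100, metric = "count",
               species_id = "SP1", abundance = 1,
               elev = 1, tmax_warm = 1, tmin_cold = 1, precip_wet = 1,
               precip_dry = 1)
  }
  prs <- data.frame(site_id = sprintf("x%d", 1:5), hpd = 1, road50 = 1,
                    road1 = 1)
  rg <- stats::setNames(rep(1, 5), .ENV <- c("elev", "tmax_warm", "tmin_cold",
                                             "precip_wet", "precip_dry"))
  # 2 baselines + 3 other sites -> 2 x 4 = 8 pairs
  rec <- mk_rec(c("primary_minimal", "primary_minimal", "cropland",
                  "cropland", "cropland"))
  p <- build_similarity_pairs(rec, prs, median_mle = 100, env_ranges = rg)
  expect_equal(nrow(p), 8)
  # closed form: n_baseline x (n_sites - 1)
  expect_equal(nrow(p), 2 * (5 - 1))
  # without reciprocal baseline pairs one direction is kept
  p1 <- build_similarity_pairs(rec, prs, median_mle = 100, env_ranges = rg,
                               include_reciprocal_baselines = FALSE)
  expect_equal(nrow(p1), 7)
  # no baseline -> no pairs
  rec2 <- mk_rec(c("cropland", "cropland", "cropland"))
  expect_equal(nrow(build_similarity_pairs(rec2, prs, 100, rg)), 0)
  # unequal effort -> study excluded
  rec3 <- mk_rec(c("primary_minimal", "cropland", "cropland"),
                 effort = c(1, 2, 1))
  expect_equal(nrow(build_similarity_pairs(rec3, prs, 100, rg)), 0)
})

test_that("standardisation yields mean 0 / sd 1 and persists its parameters", {
  fw <- fitted_world()
  ad <- fw$abundance_data
  for (v in c("ln1p_hpd", "curt_road50", "curt_road1")) {
    z <- ad$data[[paste0(v, "_z")]]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(stats::sd(z), 1, tolerance = 1e-10)
    p <- ad$params$standardize[[v]]
    expect_equal(standardize_apply(ad$data[[v]], p), z, tolerance = 1e-12)
    expect_true(all(ad$data[[v]] >= ad$params$caps[[v]][1] &
                      ad$data[[v]] <= ad$params$caps[[v]][2]))
  }
  sp <- fw$similarity_data
  expect_gt(sp$params$median_mle, 0)
  expect_length(sp$params$env_ranges, 5)
  z <- sp$data$ln_scaled_geo_z
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  # pair counts equal the closed form per eligible study
  w <- fw$world
  eligible <- split(w$sites, w$sites$study_id)
  for (st in eligible) {
    nb <- sum(st$lui == "primary_minimal")
    if (nb == 0 || length(unique(st$sampling_effort)) > 1) next
    got <- sum(sp$data$study_id == st$study_id[1])
    expect_equal(got, nb * (nrow(st) - 1))
  }
})
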