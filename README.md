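# biintact

Annual Biodiversity Intactness Index (BII) estimation from assemblage survey
data and gridded anthropogenic-pressure layers.

The BII asks: how does the average abundance of originally-present species in
a place compare with a minimally-impacted reference? `biintact` estimates it
the model-based way used for tropical and subtropical forest assessments: two
Gaussian linear mixed-effects models are fitted to a
PREDICTS-style collation of assemblage surveys —

* **total abundance**: within each study, site totals are effort-corrected,
  rescaled so the study maximum is 1, and square-root transformed; the model
  is `sqrt(abundance) ~ LUI + ln(1+HPD) + curt(road_1km) + curt(road_50km) +
  LUI:pressures + control` with random intercepts of spatial block within
  study;
* **compositional similarity**: the asymmetric abundance-based Jaccard index
  of every site against each minimally-used primary-vegetation baseline site
  in the same study, adjusted-logit transformed, modelled against the land-use
  contrast, ln-scaled geographic distance, cube-root Gower environmental
  distance and pressures (values and baseline differences), with a study
  random intercept and within-study permutation inference for the
  non-independent pairs.

Random slopes are chosen by AIC, fixed effects simplified by backward
stepwise elimination, coefficients assessed by parametric bootstrap
(abundance) or permuted likelihood ratios (similarity). Both models are then
projected over an annual pressure stack — interpolated human population
density, static two-scale road density, land-use fractions harmonized with
observed forest cover and split across use intensities, all capped to the
modelling ranges — relative to the minimally-used-primary baseline, and
multiplied into annual BII rasters. Regional reporting gives area-weighted
mean BII, log response ratios, Wilcoxon signed-rank trend tests and
GDP-association mixed models.

A seeded synthetic-world generator (`synthetic_world_config()`,
`generate_assemblages()`, `generate_pressure_stack()`) reproduces the
statistical structure the pipeline assumes, with known ground truth, so every
stage is testable without any external download.

## Worked example

```r
library(biintact)

cfg <- synthetic_world_config(n_studies = 12, sites_per_study = c(6, 10),
                              seed = 3)
w   <- generate_assemblages(cfg)
ad  <- prepare_abundance_data(w$assemblages, w$sites)
sp  <- prepare_similarity_data(w$assemblages, w$sites)

fit_ab  <- fit_abundance_model(ad, random_slopes = FALSE, simplify = FALSE)
fit_sim <- fit_similarity_model(sp)

stack <- build_pressure_stack(generate_pressure_stack(cfg))
bii   <- project_bii(fit_ab, fit_sim, stack, years = c(2001, 2012))
bii[["2001"]]
#> bii_raster 2001: mean 0.671, range [0.432, 0.900]
bii[["2012"]]
#> bii_raster 2012: mean 0.666, range [0.424, 0.899]

a01 <- aggregate_region(bii[["2001"]], stack$region_mask)
a12 <- aggregate_region(bii[["2012"]], stack$region_mask)
log_response_ratio(a01$mean_bii, a12$mean_bii)
#> [1] -0.009013239 -0.007288732 -0.006937744 -0.007347761
```

Read: in this synthetic world the modelled BII averages 67% of the
minimally-impacted reference in 2001, and every region declines slightly by
2012 (log response ratios around -0.007, i.e. about -0.5 percentage points),
driven by the imposed land-use change and population growth. The fitted model
objects print their fixed effects, random-effect SDs and selection history;
`write_bii_artifact()` serializes everything projection needs as JSON.

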