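---
title: "Estimating annual Biodiversity Intactness from assemblage data and pressure layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating annual Biodiversity Intactness from assemblage data and pressure layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biintact)
```

## The index and its two statistical components

The Biodiversity Intactness Index (BII) estimates how the average abundance of
originally-present species in a place compares with their abundance in a
minimally-impacted reference condition. `biintact` composes it, cell by cell
and year by year, as the product of two model-based quantities:

* **relative total abundance** — the prediction of a Gaussian linear
  mixed-effects model of square-root rescaled site total abundance, divided by
  the same model's prediction for the reference condition;
* **relative compositional similarity** — the prediction of a Gaussian linear
  mixed-effects model of logit-transformed *asymmetric abundance-based Jaccard
  similarity* (the proportion of a site's individuals that belong to species
  also present in a baseline site), divided by the baseline-pair prediction.

The reference condition is minimally-used primary vegetation with zero human
population density and zero road density; for similarity the baseline pair
additionally has zero environmental distance and a geographic separation equal
to the median sampling grain of the dataset. Because abundance of
originally-present species can increase, BII has no upper bound; it cannot be
negative.

## Data model

The modelling currency is an assemblage table with one row per
(study, site, species) observation. Studies are independent published surveys
that compare sites under different land uses; sites carry coordinates, a land
use (primary, secondary, plantation, cropland, pasture, urban), a use
intensity (minimal, light, intense), sampling effort, the maximum linear
extent of sampling, and five environmental covariates (elevation, maximum
temperature of the warmest month, minimum temperature of the coldest month,
precipitation of the wettest and driest months). Pressures at sites — human
population density (HPD) and road density at the 1 km and 50 km scales — come
from the gridded layers.

Land use and intensity are merged into a single LUI factor. Plantation forest
is rarely separable in global land-use layers, so it folds into secondary
vegetation: minimally-used plantation joins lightly-used secondary, and
lightly- or intensively-used plantation joins intensively-used secondary.
Primary vegetation keeps a minimal vs light+intense split and secondary keeps
all three intensities, giving eight classes with `primary_minimal` as the
reference. The same eight-level factor is used by both models and by the
projection stack — a deliberate simplification relative to analyses that give
the abundance model a finer intensity crossing, made so that every fitted
class has a matching fraction layer at projection time.

## The abundance model

Within each study, site totals are divided by sampling effort when effort
varies within the study *and* the reported metric is effort-sensitive (counts
of individuals are; density-style metrics are not), then rescaled by the study
maximum so the largest total is exactly 1, and square-root transformed.
Fixed effects are LUI, ln(1+HPD), cube-root road density at both scales, the
two-way interactions of LUI with each pressure, and the study-mean ln(1+HPD)
as a control for sampling-completeness bias near population centres; all
continuous covariates are standardised (the means and SDs are stored in the
fit for projection-time reuse). Random intercepts are spatial block nested in
study.

With the model fitted by REML, `select_random_slopes()` compares AIC across
models with each covariate in turn as a random slope within study, keeping the
structure with the lowest AIC among those that converged; differences of at
most 2 AIC units from the no-slope base count as ties and the simpler base is
kept. `backward_stepwise()` then simplifies the fixed effects under ML using
likelihood-ratio tests at alpha = 0.05 per removal, respecting marginality
(main effects stay while their interactions remain) and protecting the
sampling-bias control. The procedure names the criterion explicitly because
the literature on this pipeline specifies backward elimination without a
threshold; 0.05 is the conventional choice. Coefficient significance uses a
parametric bootstrap (`lme4::bootMer`) with percentile intervals;
non-parametric resampling of whole studies is available behind a flag. The
main-effects design is screened with generalized variance inflation factors
(threshold 5 on the squared df-scaled GVIF).

## The similarity model

For every study with at least one minimally-used primary-vegetation site, each
baseline site is compared with every other site of the study (both directions
for baseline-baseline pairs, flag-controlled, since only one direction is also
defensible). Studies whose effort varies among sites are excluded, because the
similarity measure is abundance-weighted. The response is the asymmetric
Jaccard similarity, logit-transformed after a symmetric linear compression
`x * 0.98 + 0.01` that maps 0 and 1 to finite values and is exactly
invertible; 0.01 is the adjustment magnitude the source analysis states, and
the linear-compression form is this package's choice among the
transformations consistent with it.

Covariates are the land-use contrast (the LUI class of the non-baseline site),
ln geographic distance after division by the dataset-median maximum linear
extent (co-located sites are floored at 1 m before division), cube-root Gower
environmental dissimilarity (ranges computed once over the modelling data and
persisted), each pressure at the non-baseline site *and* the
baseline-minus-site difference, and the study-mean ln(1+HPD) control, with a
study random intercept and the same AIC random-slope selection. Interactions
of the contrast with the three pressure-at-site covariates are included by
default; the full contrast-by-covariate crossing is available but routinely
unidentifiable at desk scale.

Pairs sharing sites are not independent, so likelihood-ratio tests are
anticonservative. `permutation_lrt()` therefore compares the observed ML
likelihood ratio of nested models with its distribution across datasets whose
responses are shuffled within each study (1000 permutations by default;
p = (1 + #{permuted >= observed}) / (n_perm + 1)). We permute the transformed
response; for a monotone transformation applied before fitting this is
equivalent to permuting raw similarities. Coefficient-level significance
compares observed |t| with the permuted |t| distribution — the "similar
approach" at the coefficient level. For the common case of a single random
intercept the permutation engine evaluates a closed-form profiled ML deviance
(quasi-demeaning each study by `1 - sqrt(1/(1 + n_g * lambda))` and optimising
the one-dimensional variance-ratio profile); this is algebraically the same
deviance lme4 computes, is validated against lme4 in the test suite, and
makes hundreds of thousands of permutation refits affordable. Any other
random structure falls back to `lme4::refit`.

## Pressure layers

`build_pressure_stack()` assembles, per year: HPD interpolated linearly on
the ln(1+x) scale between the 2000/2005/2010/2015 snapshots (so 2006 is
0.8 x 2005 + 0.2 x 2010 on that scale; no extrapolation outside the snapshot
range); land-use fractions harmonized against observed forest cover; and an
intensity allocation that splits each land-use fraction into
minimal/light/intense shares via a multinomial logit in ln(1+HPD) before
mapping to the merged LUI classes. Road densities (total length within 1 km
and 50 km of each cell centre per unit neighbourhood area, exact Euclidean
segment-circle clipping on the projected toy grid) are static.

Harmonization applies two rules, rule 1 first, at most one per cell: if
predicted primary exceeds observed forest cover, primary is reduced to match
and the other four classes are scaled by a common factor preserving the
five-class total; if primary + secondary fall short of observed cover, both
are scaled up proportionally and the remaining three classes scaled down,
again preserving the total. Two conventions the source rules leave open are
resolved as follows: "total preserved" means the five-class sum, and forest
cover above that sum is treated as equal to it (otherwise no
total-preserving scaling exists). Where rule 1 fires in a cell with no
non-primary area, the excess moves to secondary vegetation and is counted.
Primary vegetation is allowed to increase between years; no monotonicity is
imposed.

Before projection every covariate layer is capped to the range observed among
modelling sites on the transformed scale, so the models never extrapolate
beyond the data.

## Projection and the baseline identity

For each cell and year, the fixed-effect prediction is computed per LUI class
with the cell's capped, standardised covariates (random effects at zero,
controls at their mean), back-transformed — squared for abundance, with
negative linear predictors floored at zero first; inverse adjusted-logit for
similarity — and combined across classes weighted by the class fractions.
Combining on the natural scale is the default because downscaled fractions
describe an area mixture within the cell; combining on the link scale is
available behind a flag. The result is divided by the baseline prediction and
the two relative rasters are multiplied into BII.

Similarity projection evaluates the pressure-at-site covariates at the cell's
values and the baseline-minus-site differences at zero-minus-cell, with
geographic distance at the median sampling grain and environmental distance
zero — the projection convention implicit in the baseline definition.

One numerical convention matters for exactness: the baseline's "zero pressure"
covariates pass through the same cap-and-standardise path as projected cells.
Raw zero lies below the smallest training value for some covariates; capping
the baseline identically makes the baseline the exact prediction for a
pristine cell, so a cell that is 100% minimally-used primary vegetation with
zero pressures has BII exactly 1 in every year. This identity is asserted in
the tests.

## Regional reporting

`aggregate_region()` averages modelled cells with spherical cell-area weights
on the native grid — the same expectation as equal-area reprojection, without
resampling artefacts at toy scale — and reports the included-area fraction per
region. Trends are log response ratios ln(BII_end / BII_start) per region,
tested across regions with a Wilcoxon signed-rank test (zeros dropped, the
signed-rank convention; an all-zero set returns p = 1). GDP association fits a
linear mixed model of the log response ratio on the GDP predictor with
subregion as a random intercept, falling back to fixed subregion effects when
the random effect is singular; residuals are screened with Moran's I on
inverse-distance weights, and a Gaussian distance-decay GLS stage (fixed
subregion effects, `nlme::corGaus` with nugget) is substituted when
autocorrelation is flagged. A minimum included-area filter (e.g. 50%)
restricts the region set without ever adding regions.

## The synthetic world

The generator replaces the assemblage database and the global layers with a
seeded world whose ground truth is returned alongside the data, so parameter
recovery is checkable against the values that generated the data.

Site total abundance is generated on the square-root scale as
(1 + study effect + block effect + LUI effect + pressure slopes + residual)^2;
effects are therefore expressed in the units the abundance model estimates.
Composition uses a species-pool model: each study has a pool of native species
whose occupancy probability decays exponentially with distance from a random
niche centre at the configured `distance_decay`, plus a pool of
disturbance-adapted species absent from pristine sites. The expected native
share of a site's individuals follows an adjusted-logit linear model in the
LUI class and transformed pressures, so the asymmetric Jaccard of generated
pairs declines with pressure contrast and geographic distance the way the
similarity model assumes. Coordinates live on a unit-degree toy grid and
distances are great-circle, exercising the same code paths as real data.

Default conditions were chosen once to be realistic for this kind of
collation: between-study heterogeneity larger than within-study noise
(study SD 0.15, block SD 0.06, residual SD 0.06 on the sqrt scale; study SD
0.4, residual SD 0.35 on the logit scale), a quarter of studies with varying
effort, LUI effects ordered from light pressure to urban conversion with a
cropland effect of -0.3 on the sqrt scale, and a pristine native share of
0.95. The pressure world partitions the grid into contiguous longitude-band
regions, imposes linear primary-to-cropland conversion in named regions,
grows HPD exponentially, and draws GDP-per-capita series log-normally with a
configurable correlation to the imposed loss so the reporting stage can be
tested in null and signal regimes.

What the generator does *not* emulate: realistic biogeography, phylogenetic
structure, detection error, temporal lags in biodiversity response, and the
spatial texture of real land-use maps. Passing tests therefore demonstrate
that the estimation machinery recovers known structure under the model's own
assumptions — not that those assumptions hold for any particular real dataset.

## Numerical choices and degenerate inputs

* Adjusted logit: linear compression (`x * 0.98 + 0.01`), symmetric and
  exactly invertible; similarity 0 maps to ln(0.01/0.99) = -4.595.
* Zero geographic distance: floored at 1 m before scaling (ln needs a
  positive argument).
* Effort sensitivity: metrics labelled as counts are divided by effort when
  effort varies within a study; density-like metrics are not.
* Median maximum linear extent: computed once over the modelling dataset,
  missing values excluded.
* AIC ties (within 2 units) resolve to the simpler random structure.
* Optimizer fallbacks: nloptwrap, then bobyqa, then Nelder-Mead; a hard
  failure names the fitting step. Singular fits are tolerated (common at toy
  scale) rather than treated as failures.
* All-zero site totals rescale to zero with a warning; zero-total sites make
  similarity undefined and the pair is dropped and counted.
* Permutation p-values use the add-one convention, so the attainable floor is
  1/(n_perm + 1) and p = 0 is impossible.
* Abundance back-transformation floors negative linear predictors at zero
  before squaring, keeping predictions monotone in the predictor.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic worlds:
typically 6-30 studies of 4-15 sites for model-level checks, a 60-study
by 15-site world replicated 20 times for parameter recovery, 400 small null
worlds at 199 permutations for permutation calibration, and 16x16 to 12x48
grids over 2001-2012 for projection and reporting. These sizes were chosen so
the full pipeline is exercised many times over at desk scale; all of the
statistical behaviour they probe (calibration, recovery, identities) is
size-stable.

## Known limitations

Uncertainty is not propagated from the two models into BII maps (the two-model
structure makes this a research problem of its own). The road-density focal
geometry is exact Euclidean on a projected toy grid rather than a bit-exact
replica of GIS focal statistics. The GAM-based statistical downscaling of
coarse land use sits behind a provider interface and is not reimplemented:
the stack builder consumes per-class fraction rasters from any provider. The
intensity-allocation coefficients shipped are a documented synthetic default,
not externally fitted values. Rasters are in-memory matrices with grid
metadata; TIFF-plus-manifest export is provided, but there is no
georeferenced GeoTIFF I/O.
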