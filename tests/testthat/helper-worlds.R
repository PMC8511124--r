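# shared fixtures, generated in code; cached so several test files can reuse
# one fitted model pair without refitting

zero_effects <- function() {
  list(abundance = stats::setNames(rep(0, 8), lui_levels()),
       similarity = stats::setNames(rep(0, 8), lui_levels()))
}

null_world_config <- function(seed, n_studies = 6, sites = c(5, 7),
                              sim_residual_sd = 0.4) {
  synthetic_world_config(
    n_studies = n_studies, sites_per_study = sites,
    lui_effects = zero_effects(),
    hpd_slope = c(abundance = 0, similarity = 0),
    road50_slope = c(abundance = 0, similarity = 0),
    road1_slope = c(abundance = 0, similarity = 0),
    study_sd = 0, block_sd = 0, residual_sd = 0.05,
    sim_study_sd = 0.2, sim_residual_sd = sim_residual_sd,
    effort_varying_fraction = 0, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

# medium signal world with both models fitted; built once per test run
fitted_world <- function() {
  if (is.null(.fixture_env$fw)) {
    cfg <- synthetic_world_config(n_studies = 14, sites_per_study = c(7, 10),
                                  seed = 42)
    w <- generate_assemblages(cfg)
    ad <- prepare_abundance_data(w$assemblages, w$sites)
    sd2 <- prepare_similarity_data(w$assemblages, w$sites)
    fa <- fit_abundance_model(ad, random_slopes = FALSE, simplify = FALSE,
                              check_collinearity_warn = FALSE)
    fs <- fit_similarity_model(sd2, random_slopes = FALSE)
    pw <- generate_pressure_stack(cfg)
    st <- build_pressure_stack(pw)
    .fixture_env$fw <- list(cfg = cfg, world = w, abundance_data = ad,
                            similarity_data = sd2, fit_ab = fa, fit_sim = fs,
                            pressure_world = pw, stack = st)
  }
  .fixture_env$fw
}

# pressure world forced to pristine conditions: 100% primary vegetation,
# zero population and roads, allocation pinned to the minimal intensity
pristine_stack <- function(seed = 7, grid_shape = c(8, 8)) {
  cfg <- synthetic_world_config(n_studies = 6, sites_per_study = c(5, 7),
                                grid_shape = grid_shape, hpd_growth = 0,
                                seed = seed)
  pw <- generate_pressure_stack(cfg)
  for (y in names(pw$lu)) {
    for (k in names(pw$lu[[y]])) {
      pw$lu[[y]][[k]][] <- if (k == "primary") 1 else 0
    }
    pw$forest[[y]][] <- 1
  }
  for (y in names(pw$hpd_snapshots)) pw$hpd_snapshots[[y]][] <- 0
  pw$road1[] <- 0
  pw$road50[] <- 0
  ic <- default_intensity_coefs()
  ic$slope <- 0
  ic$intercept <- ifelse(ic$intensity == "minimal", 50, -50)
  build_pressure_stack(pw, ic)
}

# random sparse species-count vector for Jaccard fuzzing
random_counts <- function(n_species = 30, p_present = 0.3) {
  sp <- sprintf("SP%03d", seq_len(n_species))
  pres <- stats::runif(n_species) < p_present
  stats::setNames(ifelse(pres, stats::rlnorm(n_species), 0), sp)
}

# brute-force oracle: loop over species membership
jaccard_oracle <- function(ci, cj) {
  tot <- 0; shared <- 0
  for (sp in names(cj)) {
    tot <- tot + cj[[sp]]
    in_i <- sp %in% names(ci) && ci[[sp]] > 0
    if (in_i) shared <- shared + cj[[sp]]
  }
  if (tot == 0) return(NA_real_)
  shared / tot
}
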