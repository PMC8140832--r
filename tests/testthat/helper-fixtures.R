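# Shared simulated cohorts, generated once per session and reused across
# test files. All seeds fixed; every fixture is the generator's default
# study conditions unless a scenario demands otherwise.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Default study conditions: n = 500, 2 components, noise SD 5.
fx_default <- function() fx_get("default", function() {
  cfg <- generator_config(n_patients = 500, seed = 1)
  gen <- generate_cohort(cfg)
  coh <- build_cohort(gen$encounters)
  mod <- fit_fpca(coh$encounters)
  lab <- classify_decliners(mod)
  list(cfg = cfg, gen = gen, coh = coh, mod = mod, lab = lab)
})

# Low-noise, visit-dense cohort for curve/derivative recovery checks.
fx_lownoise <- function() fx_get("lownoise", function() {
  cfg <- generator_config(n_patients = 300, noise_sd = 1, visits_per_year = 3,
                          seed = 4)
  gen <- generate_cohort(cfg)
  coh <- build_cohort(gen$encounters)
  mod <- fit_fpca(coh$encounters)
  list(cfg = cfg, gen = gen, coh = coh, mod = mod)
})

# Cohort large enough to hold three centers in every size category.
fx_dashboard <- function() fx_get("dashboard", function() {
  cfg <- generator_config(n_patients = 900,
                          center_size_mix = c(small = 0.34, medium = 0.33,
                                              large = 0.33),
                          seed = 5)
  gen <- generate_cohort(cfg)
  coh <- build_cohort(gen$encounters)
  mod <- fit_fpca(coh$encounters)
  lab <- classify_decliners(mod)
  list(cfg = cfg, gen = gen, coh = coh, mod = mod, lab = lab)
})

# Scenario cohort: small centers see older patients with milder
# first-component loadings.
fx_scenario <- function() fx_get("scenario", function() {
  cfg <- generator_config(n_patients = 700, seed = 7,
                          center_size_mix = c(small = 0.5, medium = 0.3,
                                              large = 0.2),
                          center_age_shift = c(small = 6, medium = 0, large = 0),
                          center_score_shift = c(small = -18, medium = 0,
                                                 large = 0))
  gen <- generate_cohort(cfg)
  coh <- build_cohort(gen$encounters)
  mod <- fit_fpca(coh$encounters)
  lab <- classify_decliners(mod)
  list(cfg = cfg, gen = gen, coh = coh, mod = mod, lab = lab)
})

# Quick constructor for hand-made encounter tables.
make_enc <- function(pid, ages, fev = 90, year = NULL, center = "A") {
  if (is.null(year)) year <- 2000 + floor(ages - min(ages))
  data.frame(patient_id = pid, year = year, center_id = center,
             encounter_age = ages, fev1pp = fev, stringsAsFactors = FALSE)
}

# Principal angle (degrees) between two unit-norm grid functions.
principal_angle <- function(f, g, grid) {
  w <- diff(grid)[1]
  acos(min(1, abs(sum(w * f * g) / sqrt(sum(w * f^2) * sum(w * g^2))))) * 180 / pi
}

true_label_lookup <- function(gen) {
  stats::setNames(gen$truth$patients$true_label, gen$truth$patients$patient_id)
}
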