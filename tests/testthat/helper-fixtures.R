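# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the typical paediatric patient of the dosing tables
typical_patient <- function() {
  subject_covariates(id = "typical", postnatal_age = 1.4, wt = 9.9,
                     gestational_age = 38.3, ffm = 8.8, gst = 10.12)
}

# a mid-sized synthetic study (55 subjects, full 12-dose design)
study_fixture <- function(seed = 11) {
  fixture(paste0("study", seed), function() {
    pop <- generate_population(demographics_spec(n_subjects = 55),
                               seed = seed)
    truth <- population_parameters()
    ds <- generate_study_dataset(pop, truth, study_design(), seed = seed)
    list(pop = pop, truth = truth, dataset = ds)
  })
}

# a small, fast estimation problem: one eta (CL), no IOV, single-dose
# design with a handful of observations per subject
toy_spec <- function() {
  model_spec(etas = "cl", iov = FALSE, occ_breaks = numeric(),
             estimated = c("theta_cl", "omega_cl", "sigma_prop"))
}

toy_pop <- function(...) {
  population_parameters(omega_vc = 0, omega_vp = 0, pi_cl = 0,
                        s_gsh = 0, sigma_add = 0.005, ...)
}

toy_dataset <- function(n = 10, seed = 42, pop = toy_pop(),
                        obs_times = c(2, 3.5, 5.5)) {
  subjects <- generate_population(demographics_spec(n_subjects = n),
                                  seed = seed)
  set.seed(seed + 1000)
  rows <- lapply(subjects, function(cov) {
    reg <- dosing_regimen(wt_band_dose(cov$wt) * cov$wt, n_doses = 1)
    eta <- c(cl = rnorm(1, 0, pop$omega_cl), vc = 0, vp = 0)
    ind <- individual_parameters(pop, cov, eta, 0, toy_spec())
    prof <- simulate_profile(ind, reg, obs_times = obs_times,
                             k_gsh = pop$k_gsh)
    dv <- apply_residual(prof$conc, pop$sigma_prop, pop$sigma_add)
    make_event_records(cov, reg, obs_times, dv, occ_breaks = numeric())
  })
  as_dataset(do.call(rbind, rows))
}
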