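test_that("joint density reduces to its closed-form pieces", {
  pop <- toy_pop()
  cov <- typical_patient()
  reg <- dosing_regimen(10, n_doses = 1)
  # no observations: only the random-effect prior terms remain
  ev <- make_event_records(cov, reg, numeric(), numeric(),
                           occ_breaks = numeric())
  g0 <- individual_joint_density(ev, pop, eta = c(cl = 0), spec = toy_spec())
  expect_equal(g0, log(2 * pi * pop$omega_cl^2))
  # one observation equal to its prediction, additive-only error, no
  # random effects: a single Gaussian normalising constant
  pop_fix <- population_parameters(omega_cl = 0, omega_vc = 0, omega_vp = 0,
                                   pi_cl = 0, s_gsh = 0, sigma_prop = 0,
                                   sigma_add = 0.02)
  ind <- individual_parameters(pop_fix, cov)
  pr <- simulate_profile(ind, reg, obs_times = 3)
  ev1 <- make_event_records(cov, reg, 3, pr$conc, occ_breaks = numeric())
  g1 <- individual_joint_density(ev1, pop_fix, spec = toy_spec())
  expect_equal(g1, log(2 * pi * 0.02^2), tolerance = 1e-6)
  # hand-built density for a linear toy subject at a nonzero eta
  tt <- c(2, 4, 6)
  dv <- c(1.1, 0.8, 0.55)
  ev2 <- make_event_records(cov, reg, tt, dv, occ_breaks = numeric())
  eta <- 0.25
  f <- two_cpt_inf_conc(tt, ind$cl_i * exp(eta), ind$vc_i, ind$q_i,
                        ind$vp_i, reg$start_time, reg$duration, reg$amount)
  v <- (f * pop$sigma_prop)^2 + pop$sigma_add^2
  hand <- sum(log(2 * pi * v) + (dv - f)^2 / v) +
    log(2 * pi * pop$omega_cl^2) + eta^2 / pop$omega_cl^2
  got <- individual_joint_density(ev2, pop, eta = c(cl = eta),
                                  spec = toy_spec())
  expect_equal(got, hand, tolerance = 1e-5)
})

test_that("FOCE-I objective tracks Gauss-Hermite quadrature on one-eta problems", {
  cov <- typical_patient()
  reg <- dosing_regimen(10, n_doses = 1)
  tt <- c(2, 3, 5, 8)
  base <- toy_pop()
  ind0 <- individual_parameters(base, cov)
  set.seed(21)
  truth_f <- two_cpt_inf_conc(tt, ind0$cl_i * exp(0.2), ind0$vc_i, ind0$q_i,
                              ind0$vp_i, reg$start_time, reg$duration,
                              reg$amount)
  dv <- truth_f * (1 + rnorm(4, 0, 0.1))
  ev <- make_event_records(cov, reg, tt, dv, occ_breaks = numeric())
  ds <- as_dataset(ev)
  for (om in c(0.12, 0.25, 0.45)) {
    for (sg in c(0.08, 0.12, 0.2)) {
      pop <- toy_pop(omega_cl = om, sigma_prop = sg)
      foce <- as.numeric(foce_objective(ds, pop, toy_spec()))
      exact <- gh_neg2ll_one_eta(tt, dv, reg$start_time, reg$duration,
                                 reg$amount, ind0$cl_i, ind0$vc_i,
                                 ind0$q_i, ind0$vp_i, om, sg,
                                 pop$sigma_add)
      expect_lt(abs(foce - exact), 0.5)
    }
  }
})

test_that("degenerate random effects collapse the OFV to the fixed-effect -2LL", {
  cov <- typical_patient()
  reg <- dosing_regimen(10, n_doses = 1)
  tt <- c(2, 4, 7)
  dv <- c(1.2, 0.85, 0.5)
  ev <- make_event_records(cov, reg, tt, dv, occ_breaks = numeric())
  pop <- population_parameters(omega_cl = 0, omega_vc = 0, omega_vp = 0,
                               pi_cl = 0, s_gsh = 0)
  ofv <- as.numeric(foce_objective(as_dataset(ev), pop))
  f <- two_cpt_inf_conc(tt, individual_parameters(pop, cov)$cl_i,
                        individual_parameters(pop, cov)$vc_i,
                        individual_parameters(pop, cov)$q_i,
                        individual_parameters(pop, cov)$vp_i,
                        reg$start_time, reg$duration, reg$amount)
  v <- (f * pop$sigma_prop)^2 + pop$sigma_add^2
  expect_equal(ofv, sum(log(2 * pi * v) + (dv - f)^2 / v), tolerance = 1e-4)
})

test_that("fitting a toy problem converges, satisfies the information identities, and is a fixed point", {
  ds <- fixture("toyfit_ds", function() toy_dataset(n = 12, seed = 42))
  init <- toy_pop(theta_cl = 12, omega_cl = 0.35, sigma_prop = 0.2)
  ft <- fixture("toyfit", function() fit(ds, toy_spec(), init))
  expect_equal(ft$status, "converged")
  expect_equal(ft$aic, ft$ofv + 2 * ft$n_par)
  expect_equal(ft$bic, ft$ofv + ft$n_par * log(ft$n_obs))
  expect_equal(ft$n_obs, 36)
  expect_true(all(is.finite(ft$se)))
  expect_true(all(ft$rse > 0))
  expect_gte(ft$condition_number, 1)
  # recovery on this small problem is loose but should be in the ballpark
  expect_equal(ft$estimates$theta_cl, 9.57, tolerance = 0.25)
  # refitting from the optimum does not move the objective
  ft2 <- fit(ds, toy_spec(), ft$estimates,
             fit_control(hessian = FALSE))
  expect_lt(abs(ft2$ofv - ft$ofv), 0.01)
})

test_that("a strong true covariate is selected and a duplicate term is not", {
  # data where clearance genuinely scales with GST activity
  set.seed(77)
  subjects <- generate_population(demographics_spec(n_subjects = 16),
                                  seed = 77)
  pop <- toy_pop()
  rows <- lapply(subjects, function(cov) {
    reg <- dosing_regimen(wt_band_dose(cov$wt) * cov$wt, n_doses = 1)
    ind <- individual_parameters(pop, cov,
                                 eta = c(cl = rnorm(1, 0, pop$omega_cl)),
                                 kappa = 0, spec = toy_spec())
    ind$cl_i <- ind$cl_i * (cov$gst / 9.2)^0.8
    prof <- simulate_profile(ind, reg, obs_times = c(2, 3.5, 5.5))
    dv <- apply_residual(prof$conc, pop$sigma_prop, pop$sigma_add)
    make_event_records(cov, reg, c(2, 3.5, 5.5), dv,
                       occ_breaks = numeric())
  })
  ds <- as_dataset(do.call(rbind, rows))
  gst_term <- list(param = "cl", cov = "GST", form = "power", theta = 0.1,
                   ref = 9.2, name = "beta_cl_gst")
  dup_term <- list(param = "cl", cov = "GST", form = "power", theta = 0.1,
                   ref = 9.2, name = "beta_cl_gst2")
  sel <- covariate_step(ds, toy_spec(), list(gst_term, dup_term), pop)
  nm <- vapply(sel$spec$covariates, function(tm) tm$name, character(1))
  expect_true("beta_cl_gst" %in% nm || "beta_cl_gst2" %in% nm)
  expect_lt(length(nm), 2)  # the duplicate adds nothing
  first_in <- sel$log[sel$log$step == "forward" &
                        sel$log$action == "candidate", ][1, ]
  expect_gt(first_in$delta_ofv, 3.84 * 3)  # positive control is decisive
  th <- sel$spec$covariates[[1]]$theta
  expect_equal(th, 0.8, tolerance = 0.35)
})

test_that("shrinkage and CWRES are calibrated when the model is the truth", {
  sf <- study_fixture()
  evalspec <- model_spec(estimated = character())
  ft <- fixture("eval_fit", function()
    fit(sf$dataset, evalspec, sf$truth, fit_control(hessian = FALSE)))
  sh <- shrinkage(ft)
  # ~10 informative samples per subject: modest eta-CL shrinkage
  expect_lt(sh$eta[["eta_cl"]], 30)
  expect_gt(sh$eta[["eta_cl"]], -15)
  expect_true(is.finite(sh$eps))
  cw <- cwres(ft)
  expect_equal(nrow(cw), sum(sf$dataset$EVID == 0 & sf$dataset$MDV == 0))
  expect_lt(abs(mean(cw$CWRES)), 0.1)
  expect_gt(sd(cw$CWRES), 0.85)
  expect_lt(sd(cw$CWRES), 1.15)
  # inflating all observations leaves a systematic positive residual
  ds2 <- sf$dataset
  ds2$DV[ds2$EVID == 0] <- ds2$DV[ds2$EVID == 0] * 2
  ft2 <- fit(as_dataset(as.data.frame(ds2)), evalspec, sf$truth,
             fit_control(hessian = FALSE))
  expect_gt(mean(cwres(ft2)$CWRES), 0.5)
})

test_that("GOF tables mirror the observations and flag almost no extreme residuals", {
  sf <- study_fixture()
  ft <- fixture("eval_fit", function()
    fit(sf$dataset, model_spec(estimated = character()), sf$truth,
        fit_control(hessian = FALSE)))
  gof <- gof_tables(ft)
  expect_named(gof, c("ID", "TIME", "DV", "PRED", "IPRED", "IWRES", "CWRES"))
  expect_equal(nrow(gof), ft$n_obs)
  expect_lt(mean(abs(gof$CWRES) > 4, na.rm = TRUE), 0.01)
  expect_gt(cor(gof$DV, gof$IPRED), 0.9)
  # a noise-free, variability-free toy reproduces DV exactly
  pop0 <- population_parameters(omega_cl = 0, omega_vc = 0, omega_vp = 0,
                                pi_cl = 0, sigma_prop = 0,
                                sigma_add = 1e-6)
  cov <- typical_patient()
  reg <- dosing_regimen(10, n_doses = 1)
  ind <- individual_parameters(pop0, cov)
  prof <- simulate_profile(ind, reg, obs_times = c(2, 5))
  ev <- make_event_records(cov, reg, c(2, 5), prof$conc,
                           occ_breaks = numeric())
  ft0 <- fit(as_dataset(ev), model_spec(estimated = character()), pop0,
             fit_control(hessian = FALSE))
  gof0 <- gof_tables(ft0)
  expect_equal(gof0$PRED, gof0$DV, tolerance = 1e-5)
})
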