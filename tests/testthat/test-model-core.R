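pop_default <- population_parameters()

test_that("individual parameters reproduce the typical-subject chain", {
  ref <- reference_subject()
  adult <- subject_covariates("adult", "male", postnatal_age = 30,
                              wt = 70, ht = 176, gestational_age = 40,
                              gst = 9.2)
  ind <- individual_parameters(pop_default, adult)
  # allometric ratio is exactly 1 at the standard subject
  fmat <- maturation_fraction(adult$pma, pop_default$tm50, pop_default$hill)
  expect_equal(ind$cl_i, pop_default$theta_cl * fmat, tolerance = 1e-10)
  expect_gt(fmat, 0.98)
  expect_equal(ind$vc_i, pop_default$theta_vc)
  # typical paediatric patient: independent hand-calculation chain
  tp <- typical_patient()
  ind_tp <- individual_parameters(pop_default, tp)
  nfm_cl <- 8.8 + 0.905 * (9.9 - 8.8)
  nfm_cl_std <- ref$ffm + 0.905 * (70 - ref$ffm)
  cl_hand <- 9.57 * (nfm_cl / nfm_cl_std)^0.75 *
    maturation_fraction(38.3 + 1.4 * 52.1775, 45, 1.11)
  expect_equal(ind_tp$cl_i, cl_hand, tolerance = 1e-10)
  expect_equal(ind_tp$cl_i, 1.63, tolerance = 0.01)
  expect_equal(ind_tp$s_gsh_i,
               0.00259 * gst_multiplier(10.12, 0.28, 9.2))
})

test_that("log-normal effects multiply and zero effects are the fixed point", {
  tp <- typical_patient()
  i0 <- individual_parameters(pop_default, tp)
  i1 <- individual_parameters(pop_default, tp,
                              eta = c(cl = 0.3, vc = -0.2, vp = 0.1))
  expect_equal(i1$cl_i, i0$cl_i * exp(0.3))
  expect_equal(i1$vc_i, i0$vc_i * exp(-0.2))
  expect_equal(i1$vp_i, i0$vp_i * exp(0.1))
  expect_equal(i1$q_i, i0$q_i)  # Q carries no random effect
  expect_error(individual_parameters(pop_default, tp, eta = c(cl = NaN)),
               "finite")
})

test_that("size metric candidates all normalise to 1 at the reference adult", {
  adult <- subject_covariates("adult", "male", postnatal_age = 30, wt = 70,
                              ht = 176, gestational_age = 40)
  for (metric in c("WT", "BSA", "FFM", "NFM")) {
    sp <- model_spec(size_metric = metric, maturation = FALSE)
    ind <- individual_parameters(pop_default, adult, spec = sp)
    expect_equal(ind$cl_i, pop_default$theta_cl, tolerance = 1e-9)
  }
})

test_that("model derivatives satisfy equilibria and mass balance", {
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  # drug-free equilibrium: everything quiet
  d0 <- pk_rhs(0, c(0, 0, 1, 0), ind, infusion_rate = 0)
  expect_equal(unname(d0), rep(0, 4))
  # no elimination: total drug mass grows at the infusion rate
  ind_nocl <- ind; ind_nocl$cl_i <- 1e-12
  d1 <- pk_rhs(0, c(5, 2, 1, 0), ind_nocl, infusion_rate = 3)
  expect_equal(d1[["a_central"]] + d1[["a_periph"]], 3, tolerance = 1e-9)
  # depletion switch-off: pool relaxes to baseline at rate k_gsh
  ind_nogsh <- ind; ind_nogsh$s_gsh_i <- 0
  d2 <- pk_rhs(0, c(5, 2, 0.8, 0), ind_nogsh, infusion_rate = 0,
               k_gsh = 0.1)
  expect_equal(d2[["a_gsh"]], 0.1 * (1 - 0.8))
  # depletion term is negative when drug is present
  d3 <- pk_rhs(0, c(5, 2, 1, 0), ind, infusion_rate = 0)
  expect_lt(d3[["a_gsh"]], 0)
})

test_that("linear limit matches the analytic superposition to 1e-4", {
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  ind$s_gsh_i <- 0  # switch off the GSH coupling
  reg <- dosing_regimen(11.88, n_doses = 12)
  tt <- c(2, 2.5, 3, 4, 6, 30, 66, 68, 70, 74, 78, 95)
  prof <- simulate_profile(ind, reg, obs_times = tt)
  ana <- two_cpt_inf_conc(tt, ind$cl_i, ind$vc_i, ind$q_i, ind$vp_i,
                          reg$start_time, reg$duration, reg$amount)
  expect_equal(prof$conc, ana, tolerance = 1e-4)
})

test_that("compiled integrator agrees with an independent stiff solver on the coupled system", {
  skip_if_not_installed("deSolve")
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  ind$s_gsh_i <- 0.05  # exaggerated depletion to stress the coupling
  reg <- dosing_regimen(11.88, n_doses = 3)
  tt <- c(1, 2, 4, 6, 8, 12, 14, 20)
  prof <- simulate_profile(ind, reg, obs_times = tt)
  rhs_ds <- function(t, y, p) {
    rate <- sum(ifelse(t > reg$start_time &
                         t < reg$start_time + reg$duration,
                       reg$amount / reg$duration, 0))
    list(pk_rhs(t, y, ind, rate, k_gsh = 0.1))
  }
  sol <- deSolve::lsoda(c(0, 0, 1, 0), c(0, tt), rhs_ds, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(prof$conc, sol[-1, 2] / ind$vc_i, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(prof$gsh, sol[-1, 4], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("single-dose AUC equals dose over clearance without depletion", {
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  ind$s_gsh_i <- 0
  reg <- dosing_regimen(10, n_doses = 1)
  prof <- simulate_profile(ind, reg, horizon = 400)
  expect_equal(prof$cauc, 10 / ind$cl_i, tolerance = 1e-4)
  # 16-dose regimen: total dose over clearance
  reg16 <- dosing_regimen(9.9, n_doses = 16)
  prof16 <- simulate_profile(ind, reg16, horizon = 400)
  expect_equal(prof16$cauc, 16 * 9.9 / ind$cl_i, tolerance = 1e-3)
})

test_that("GSH pool stays in (0, 1], recovers after washout, and raises exposure", {
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  reg <- dosing_regimen(11.88, n_doses = 16)
  tt <- seq(0.5, 250, by = 0.5)
  prof <- simulate_profile(ind, reg, obs_times = tt, horizon = 250)
  expect_true(all(prof$gsh > 0 & prof$gsh <= 1))
  expect_gt(prof$gsh_min, 0)
  expect_lt(prof$gsh_min, 1)        # some depletion does occur
  expect_gt(prof$gsh[length(tt)], 0.999)  # recovery ~158 h after last dose
  expect_true(all(diff(prof$auc) >= 0))   # AUC state is non-decreasing
  # depletion lowers effective clearance, so exposure exceeds the linear case
  ind0 <- ind; ind0$s_gsh_i <- 0
  prof0 <- simulate_profile(ind0, reg)
  expect_gt(simulate_profile(ind, reg)$cauc, prof0$cauc)
})

test_that("dose proportionality is exact without depletion, super-proportional with it", {
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  lin <- ind; lin$s_gsh_i <- 0
  tt <- c(2, 6, 30, 70)
  r1 <- dosing_regimen(9.9, n_doses = 12)
  r2 <- dosing_regimen(19.8, n_doses = 12)
  p1 <- simulate_profile(lin, r1, obs_times = tt)
  p2 <- simulate_profile(lin, r2, obs_times = tt)
  expect_equal(p2$conc, 2 * p1$conc, tolerance = 1e-6)
  expect_equal(p2$cauc, 2 * p1$cauc, tolerance = 1e-6)
  g1 <- simulate_profile(ind, r1)
  g2 <- simulate_profile(ind, r2)
  expect_gt(g2$cauc / g1$cauc, 2)  # cAUC ratio exceeds the dose ratio
})

test_that("exposure is monotone in clearance, depletion scale and GST slope", {
  tp <- typical_patient()
  reg <- dosing_regimen(11.88, n_doses = 12)
  cauc_at <- function(mod) {
    ind <- individual_parameters(mod$pop %||% pop_default, tp)
    if (!is.null(mod$cl_mult)) ind$cl_i <- ind$cl_i * mod$cl_mult
    if (!is.null(mod$sgsh)) ind$s_gsh_i <- mod$sgsh
    simulate_profile(ind, reg)$cauc
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  by_cl <- vapply(c(0.6, 0.8, 1, 1.3, 1.7),
                  function(m) cauc_at(list(cl_mult = m)), numeric(1))
  expect_true(all(diff(by_cl) < 0))
  by_sgsh <- vapply(c(0, 0.001, 0.005, 0.02),
                    function(s) cauc_at(list(sgsh = s)), numeric(1))
  expect_true(all(diff(by_sgsh) > 0))
  by_gst <- vapply(c(0, 0.28, 0.6), function(th)
    cauc_at(list(pop = population_parameters(theta_gst = th))), numeric(1))
  expect_true(all(diff(by_gst) > 0))  # higher slope, more depletion at GST>ref
})

test_that("regimen validation and Cmax windows behave", {
  tp <- typical_patient()
  ind <- individual_parameters(pop_default, tp)
  reg <- dosing_regimen(11.88, n_doses = 16)
  prof <- simulate_profile(ind, reg, cmax_tmax = 6)
  expect_lt(prof$cmax_window, prof$cmax)  # accumulation raises later peaks
  expect_equal(prof$cmax,
               simulate_profile(ind, reg)$cmax)
  expect_error(simulate_profile(ind, reg[c(3, 1, 2), ]), "sorted")
  expect_error(dosing_regimen(-1, 2), "non-negative")
  expect_error(dosing_regimen(1, 2, duration = 0), "positive")
})

test_that("residual model has the stated mean and variance", {
  set.seed(99)
  y <- apply_residual(rep(1, 1e5), 0.111, 0.0166)
  expect_equal(mean(y), 1, tolerance = 0.005)
  expect_equal(sd(y), sqrt(0.111^2 + 0.0166^2), tolerance = 0.01)
  expect_equal(sd(y), 0.1122, tolerance = 0.01)
  expect_equal(apply_residual(c(0.5, 2), 0, 0), c(0.5, 2))
  set.seed(1)
  z <- apply_residual(rep(0, 2e4), 0.5, 0.02)
  expect_equal(sd(z), 0.02, tolerance = 0.02)
  expect_error(apply_residual(1, -0.1, 0), "non-negative")
})
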