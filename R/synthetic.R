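#' Demographic envelope for virtual paediatric populations
#'
#' Describes the joint covariate distribution the generator draws from,
#' matching the transplant cohort's envelope: ages 0.2-14.1 y with median
#' 1.4, weights 2.9-29.5 kg (median 9.9 at the median age), heights
#' 52-147 cm, GST activity 0.9-20.7 nmol/min/mL with median 9.2, and
#' gestational ages around 38.3 weeks. Weight and height come from smooth
#' age-growth reference curves (monotone splines anchored from 4.5 kg at
#' 0.2 y to 45 kg at 14 y, deliberately lean as in the transplant cohort)
#' with lognormal subject-level noise, truncated to the stated ranges. GST
#' is lognormal (meanlog ln 9.2, sdlog 0.55) truncated to its range, with
#' no imposed age correlation. Only marginals are targeted; the true joint
#' distribution of the real cohort is unknown.
#'
#' @param n_subjects number of virtual subjects.
#' @param age_range,age_median years.
#' @param age_sdlog lognormal sdlog of the age distribution.
#' @param male_frac proportion of males.
#' @param gage_mean,gage_sd,gage_range gestational age (weeks).
#' @param gst_meanlog,gst_sdlog,gst_range GST activity distribution.
#' @param wt_range,ht_range truncation ranges (kg, cm).
#' @param wt_cv,ht_cv lognormal noise around the growth curves.
#' @param comed_prev prevalence of fludarabine co-medication.
#' @return object of class `demographics_spec`.
#' @export
demographics_spec <- function(n_subjects = 55, age_range = c(0.2, 14.1),
                              age_median = 1.4, age_sdlog = 1.1,
                              male_frac = 40 / 55, gage_mean = 38.3,
                              gage_sd = 1.0, gage_range = c(32, 42),
                              gst_meanlog = log(9.2), gst_sdlog = 0.55,
                              gst_range = c(0.9, 20.7),
                              wt_range = c(2.9, 29.5),
                              ht_range = c(52, 147), wt_cv = 0.15,
                              ht_cv = 0.04, comed_prev = 0.5) {
  if (n_subjects < 0) stop("n_subjects must be non-negative")
  if (age_range[1] <= 0 || diff(age_range) < 0) stop("invalid age_range")
  spec <- as.list(environment())
  class(spec) <- "demographics_spec"
  spec
}

# lean paediatric growth references (age in years -> kg / cm)
growth_wt <- function(age) {
  a <- c(0.2, 0.5, 1, 1.4, 2, 4, 6, 10, 14)
  w <- c(4.5, 6.5, 8.8, 9.9, 11.5, 15, 18.5, 27, 45)
  stats::splinefun(log(a), log(w), method = "monoH.FC")(log(age)) |> exp()
}
growth_ht <- function(age) {
  a <- c(0.2, 0.5, 1, 1.4, 2, 4, 6, 10, 14)
  h <- c(56, 63, 72, 76, 82, 96, 108, 130, 155)
  stats::splinefun(log(a), log(h), method = "monoH.FC")(log(age)) |> exp()
}

# draw from a truncated distribution by rejection (vectorised)
rtrunc <- function(n, rfun, lo, hi, max_iter = 1000) {
  out <- numeric(0)
  for (i in seq_len(max_iter)) {
    x <- rfun(max(2 * n, 10))
    out <- c(out, x[x >= lo & x <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("empty truncation region: generation error")
}

#' Generate a virtual population
#'
#' Draws subject covariates from a [demographics_spec()]; FFM is computed
#' with [compute_ffm()] from the sampled height, weight and sex.
#'
#' @param spec a `demographics_spec`.
#' @param seed integer seed; the same seed reproduces the same population.
#' @return list of [subject_covariates()].
#' @export
generate_population <- function(spec = demographics_spec(), seed = 1) {
  set.seed(seed)
  n <- spec$n_subjects
  if (n == 0) return(list())
  age <- rtrunc(n, function(m) stats::rlnorm(m, log(spec$age_median),
                                             spec$age_sdlog),
                spec$age_range[1], spec$age_range[2])
  sex <- ifelse(stats::runif(n) < spec$male_frac, "male", "female")
  gage <- rtrunc(n, function(m) stats::rnorm(m, spec$gage_mean, spec$gage_sd),
                 spec$gage_range[1], spec$gage_range[2])
  gst <- rtrunc(n, function(m) stats::rlnorm(m, spec$gst_meanlog,
                                             spec$gst_sdlog),
                spec$gst_range[1], spec$gst_range[2])
  wt <- ht <- numeric(n)
  for (i in seq_len(n)) {
    wt[i] <- rtrunc(1, function(m) growth_wt(age[i]) *
                      stats::rlnorm(m, 0, spec$wt_cv),
                    spec$wt_range[1], spec$wt_range[2])
    ht[i] <- rtrunc(1, function(m) growth_ht(age[i]) *
                      stats::rlnorm(m, 0, spec$ht_cv),
                    spec$ht_range[1], spec$ht_range[2])
  }
  comed <- stats::runif(n) < spec$comed_prev
  lapply(seq_len(n), function(i)
    subject_covariates(id = sprintf("S%03d", i), sex = sex[i],
                       postnatal_age = age[i], wt = wt[i], ht = ht[i],
                       gestational_age = gage[i], gst = gst[i],
                       comedication = if (comed[i]) "fludarabine"
                                      else character()))
}

#' Study design of the 12-dose sampling schedule
#'
#' The paediatric conditioning design: 12 doses as 2-h infusions every 6 h,
#' 0.8-1.2 mg/kg by weight band; samples at 2, 2.5, 3, 4 and 6 h after the
#' start of dose 1, pre-dose troughs before doses 6 and 12, and after dose
#' 12 either 2/4/8 h (group A) or 2/6/12 h (group B) past the infusion
#' start, split ~50/50. Observations below the quantification limit
#' (0.010 mg/L) are excluded. Occasion windows split at 6, 36 and 66 h
#' (dose-1 profile, pre-dose-6 trough, pre-dose-12 trough, post-dose-12
#' profile).
#'
#' @param n_doses,interval,duration regimen structure (h).
#' @param dose1_samples hours after the start of dose 1.
#' @param trough_doses dose numbers preceded by a trough sample.
#' @param d12_group_a,d12_group_b hours after the start of the last dose.
#' @param occ_breaks occasion boundaries (h).
#' @param lloq lower limit of quantification (mg/L).
#' @return object of class `study_design`.
#' @export
study_design <- function(n_doses = 12, interval = 6, duration = 2,
                         dose1_samples = c(2, 2.5, 3, 4, 6),
                         trough_doses = c(6, 12),
                         d12_group_a = c(2, 4, 8),
                         d12_group_b = c(2, 6, 12),
                         occ_breaks = c(6, 36, 66), lloq = 0.010) {
  d <- as.list(environment())
  class(d) <- "study_design"
  d
}

# scheduled observation times for one subject (group "A" or "B")
design_times <- function(design, group = "A") {
  last_start <- (design$n_doses - 1) * design$interval
  c(design$dose1_samples,
    (design$trough_doses - 1) * design$interval,
    last_start + (if (group == "A") design$d12_group_a else design$d12_group_b))
}

#' Generate a full synthetic study dataset
#'
#' Simulates the study for a virtual population: weight-band doses
#' (0.8-1.2 mg/kg) over the 12-dose regimen, subject-level eta and
#' per-occasion kappa draws, concentrations at the scheduled times with
#' combined residual error, and exclusion of below-quantification values
#' (kept as `MDV = 1` rows). Group A/B membership alternates.
#'
#' @param pop list of [subject_covariates()] from [generate_population()].
#' @param params [population_parameters()] used as generative truth.
#' @param design [study_design()].
#' @param seed integer seed.
#' @param spec [model_spec()] governing the covariate model.
#' @return a [as_dataset()] event-record table, with the per-subject
#'   simulation truth in `attr(, "truth")`.
#' @export
generate_study_dataset <- function(pop, params = population_parameters(),
                                   design = study_design(), seed = 1,
                                   spec = model_spec()) {
  set.seed(seed + 1L)
  n_occ <- length(design$occ_breaks) + 1
  rows <- vector("list", length(pop))
  truth <- vector("list", length(pop))
  for (i in seq_along(pop)) {
    cov <- pop[[i]]
    mgkg <- wt_band_dose(cov$wt)
    reg <- dosing_regimen(mgkg * cov$wt, design$n_doses, design$interval,
                          design$duration)
    eta <- c(cl = stats::rnorm(1, 0, params$omega_cl),
             vc = stats::rnorm(1, 0, params$omega_vc),
             vp = stats::rnorm(1, 0, params$omega_vp))
    kappa <- if (isTRUE(spec$iov))
      stats::rnorm(n_occ, 0, params$pi_cl) else rep(0, n_occ)
    ind <- individual_parameters(params, cov, eta, kappa, spec)
    tt <- design_times(design, if (i %% 2 == 1) "A" else "B")
    prof <- simulate_profile(ind, reg, obs_times = tt, k_gsh = params$k_gsh,
                             occ_breaks = design$occ_breaks)
    dv <- apply_residual(prof$conc, params$sigma_prop, params$sigma_add)
    dv[dv < design$lloq] <- NA_real_  # BQL: excluded from DV rows
    rows[[i]] <- make_event_records(cov, reg, tt, dv, design$occ_breaks)
    truth[[i]] <- list(id = cov$id, eta = eta, kappa = kappa,
                       dose_mgkg = mgkg)
  }
  ds <- as_dataset(do.call(rbind, rows))
  attr(ds, "truth") <- truth
  ds
}
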