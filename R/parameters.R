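#' Reference (standard) adult subject
#'
#' Structural parameters are standardised to a 70 kg, 176 cm male adult.
#' The standard fat-free mass follows from [compute_ffm()]; the standard
#' normal fat mass uses the same fat-mass fraction as the individual, so the
#' allometric ratio is exactly 1 for the standard subject.
#'
#' @return list with `wt`, `ht`, `sex`, `ffm`.
#' @export
reference_subject <- function() {
  wt <- 70; ht <- 176; sex <- "male"
  list(wt = wt, ht = ht, sex = sex, ffm = compute_ffm(wt, ht, sex))
}

#' Population parameters of the final semi-mechanistic model
#'
#' All fixed effects, variance components and structural constants in one
#' place. Defaults are the final-model estimates: typical clearance and
#' volumes standardised to the 70 kg adult, NFM fat-mass fractions for
#' clearance- and volume-like parameters, maturation TM50/Hill, the fixed
#' GSH depletion scale `s_gsh` (h/mg, scaled to a 1 L central volume), the
#' exponential GST-activity slope on `s_gsh` centred at the cohort median
#' activity, log-scale SDs of between-subject (`omega_*`) and inter-occasion
#' (`pi_cl`) effects, and the combined residual-error magnitudes. `k_gsh` is
#' the GSH turnover rate (1/h), a configuration constant of the resynthesis
#' model that is not identifiable from concentration data alone.
#'
#' @param ... named overrides of any default.
#' @return object of class `population_parameters`.
#' @examples
#' pop <- population_parameters()
#' pop$theta_cl # 9.57 L/h at standard adult size
#' @export
population_parameters <- function(...) {
  p <- list(
    theta_cl = 9.57,    # L/h
    theta_vc = 28.2,    # L
    theta_q = 8.16,     # L/h
    theta_vp = 16.1,    # L
    ffat_cl = 0.905,
    ffat_vc = 0.687,
    tm50 = 45.0,        # weeks PMA
    hill = 1.11,
    s_gsh = 0.00259,    # h/mg, fixed
    theta_gst = 0.28,
    gst_ref = 9.2,      # nmol/min/mL
    k_gsh = 0.1,        # 1/h, configuration constant
    omega_cl = 0.232,
    omega_vc = 0.156,
    omega_vp = 0.400,
    pi_cl = 0.107,
    sigma_prop = 0.111,
    sigma_add = 0.0166  # mg/L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_population_parameters(p)
  class(p) <- "population_parameters"
  p
}

validate_population_parameters <- function(p) {
  pos <- c("theta_cl", "theta_vc", "theta_q", "theta_vp", "tm50", "hill",
           "gst_ref", "k_gsh")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(nm, " must be positive")
  nonneg <- c("ffat_cl", "ffat_vc", "s_gsh", "omega_cl", "omega_vc",
              "omega_vp", "pi_cl", "sigma_prop", "sigma_add")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(nm, " must be non-negative")
  invisible(p)
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("<population_parameters>\n")
  cat(sprintf("  CL %.3g L/h  Vc %.3g L  Q %.3g L/h  Vp %.3g L (70-kg standard)\n",
              x$theta_cl, x$theta_vc, x$theta_q, x$theta_vp))
  cat(sprintf("  Ffat(CL) %.3g  Ffat(Vc) %.3g  TM50 %.3g wk  Hill %.3g\n",
              x$ffat_cl, x$ffat_vc, x$tm50, x$hill))
  cat(sprintf("  S_GSH %.3g h/mg  GST slope %.3g (ref %.3g)  k_GSH %.3g 1/h\n",
              x$s_gsh, x$theta_gst, x$gst_ref, x$k_gsh))
  cat(sprintf("  BSV: CL %.1f%%  Vc %.1f%%  Vp %.1f%% | IOV CL %.1f%% | RUV %.1f%% + %.4g mg/L\n",
              100 * x$omega_cl, 100 * x$omega_vc, 100 * x$omega_vp,
              100 * x$pi_cl, 100 * x$sigma_prop, x$sigma_add))
  invisible(x)
}

# size-descriptor value for one subject and its standard-subject value
size_metric_values <- function(cov, metric, ffat) {
  ref <- reference_subject()
  switch(metric,
    WT = c(cov$wt, ref$wt),
    BSA = c(compute_bsa(cov$wt, if (is.null(cov$ht)) stop("BSA needs ht") else cov$ht),
            compute_bsa(ref$wt, ref$ht)),
    FFM = c(cov$ffm, ref$ffm),
    NFM = c(compute_nfm(cov$ffm, cov$wt, ffat),
            compute_nfm(ref$ffm, ref$wt, ffat)),
    stop("unknown size metric: ", metric))
}

# multiplicative covariate term used by the stepwise covariate machinery
covariate_term <- function(x, theta, ref, form) {
  switch(form,
    linear = 1 + theta * (x / ref - 1),
    exponential = exp(theta * (x / ref - 1)),
    power = (x / ref)^theta,
    fractional = 1 + theta * x,  # x is a 0/1 indicator
    stop("unknown covariate form: ", form))
}

#' Realised individual parameters
#'
#' Applies the covariate model and random effects to the population
#' parameters:
#' \deqn{CL_i = \theta_{CL}\,(NFM_{CL}/NFM_{CL,std})^{0.75}\,F_{mat}\,e^{\eta_{CL}}}
#' \deqn{V_{c,i} = \theta_{Vc}\,(NFM_{Vc}/NFM_{Vc,std})\,e^{\eta_{Vc}}}
#' with Q scaled like clearance but carrying no random effect or maturation,
#' Vp scaled like volume with its own eta, and the subject's GSH depletion
#' scale `s_gsh_i = s_gsh * gst_multiplier(GST)`. Allometric exponents are
#' fixed at the theory-based 0.75 (clearance-like) and 1 (volume-like).
#' Per-occasion IOV deviates `kappa` are carried on the object and enter the
#' simulation as piecewise-constant multipliers `exp(kappa_k)` on CL over the
#' occasion windows; with a single occasion this is the usual
#' `exp(eta_CL + kappa)` model.
#'
#' @param pop [population_parameters()].
#' @param cov [subject_covariates()].
#' @param eta named numeric vector of log-scale deviations (`cl`, `vc`, `vp`;
#'   missing names are treated as 0).
#' @param kappa numeric vector of per-occasion log-scale IOV deviations on CL
#'   (scalar for a single occasion).
#' @param spec optional [model_spec()] controlling the size metric and which
#'   covariate terms are active.
#' @return object of class `individual_parameters` with elements `cl_i`,
#'   `vc_i`, `q_i`, `vp_i`, `s_gsh_i`, `eta`, `kappa`.
#' @export
individual_parameters <- function(pop, cov, eta = c(cl = 0, vc = 0, vp = 0),
                                  kappa = 0, spec = NULL) {
  if (is.null(spec)) spec <- model_spec()
  e <- c(cl = 0, vc = 0, vp = 0)
  if (length(eta)) {
    if (is.null(names(eta)) && length(eta) == 3) names(eta) <- c("cl", "vc", "vp")
    e[names(eta)] <- eta
  }
  if (any(!is.finite(c(e, kappa)))) stop("random effects must be finite")
  sm_cl <- size_metric_values(cov, spec$size_metric, pop$ffat_cl)
  sm_v <- size_metric_values(cov, spec$size_metric, pop$ffat_vc)
  fsize_cl <- (sm_cl[1] / sm_cl[2])^0.75
  fsize_v <- sm_v[1] / sm_v[2]
  fmat <- if (isTRUE(spec$maturation))
    maturation_fraction(cov$pma, pop$tm50, pop$hill) else 1
  cl_i <- pop$theta_cl * fsize_cl * fmat * exp(e[["cl"]])
  vc_i <- pop$theta_vc * fsize_v * exp(e[["vc"]])
  q_i <- pop$theta_q * fsize_cl
  vp_i <- pop$theta_vp * fsize_v * exp(e[["vp"]])
  s_gsh_i <- pop$s_gsh *
    (if (isTRUE(spec$gst_covariate))
       gst_multiplier(cov$gst, pop$theta_gst, pop$gst_ref) else 1)
  # additional stepwise covariate terms
  for (term in spec$covariates) {
    x <- cov[[tolower(term$cov)]]
    if (is.null(x)) x <- cov[[term$cov]]
    if (is.null(x)) stop("covariate not found on subject: ", term$cov)
    mult <- covariate_term(x, term$theta, term$ref, term$form)
    if (mult <= 0) mult <- 1e-6  # guard linear forms against sign flips
    tgt <- paste0(term$param, "_i")
    out_name <- switch(term$param, cl = "cl_i", vc = "vc_i", vp = "vp_i",
                       q = "q_i", stop("unknown covariate target"))
    assign(out_name, get(out_name) * mult)
  }
  out <- list(cl_i = unname(cl_i), vc_i = unname(vc_i), q_i = unname(q_i),
              vp_i = unname(vp_i), s_gsh_i = unname(s_gsh_i),
              eta = e, kappa = kappa)
  if (any(unlist(out[1:4]) <= 0)) stop("realised parameters must be positive")
  if (out$s_gsh_i < 0) stop("s_gsh_i must be non-negative")
  class(out) <- "individual_parameters"
  out
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf("<individual_parameters> CL %.3g L/h  Vc %.3g L  Q %.3g L/h  Vp %.3g L  S_GSH %.3g h/mg\n",
              x$cl_i, x$vc_i, x$q_i, x$vp_i, x$s_gsh_i))
  invisible(x)
}
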