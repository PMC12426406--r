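#' Model specification for estimation and simulation
#'
#' Describes one candidate model: the body-size descriptor used for
#' allometric scaling, whether the maturation function and the GST covariate
#' on the depletion scale are active, which random effects are carried, the
#' occasion windows used for inter-occasion variability, any additional
#' stepwise covariate terms, and which population parameters the fitter
#' estimates (all others stay at their initial values).
#'
#' The default is the final model: NFM allometry, PMA maturation on CL, GST
#' on `s_gsh`, etas on CL/Vc/Vp, IOV on CL across the four sampling
#' occasions of the 12-dose design (windows split at 6, 36 and 66 h:
#' dose-1 profile, pre-dose-6 trough, pre-dose-12 trough, post-dose-12
#' profile). The structural covariate parameters (`ffat_cl`, `ffat_vc`,
#' `tm50`, `hill`, `theta_gst`) are held fixed by default: identifying
#' maturation and body-composition parameters requires data spanning
#' neonates to adults, which a single paediatric cohort cannot provide.
#'
#' @param size_metric one of `"WT"`, `"BSA"`, `"FFM"`, `"NFM"`.
#' @param maturation logical, apply the PMA maturation fraction to CL.
#' @param gst_covariate logical, apply the GST multiplier to `s_gsh`.
#' @param iov logical, inter-occasion variability on CL.
#' @param etas character subset of `c("cl", "vc", "vp")`.
#' @param occ_breaks numeric vector of occasion window boundaries (h).
#' @param covariates list of additional covariate terms, each a list with
#'   `param` (`"cl"`, `"vc"`, `"vp"`, `"q"`), `cov` (column name), `form`
#'   (`"linear"`, `"exponential"`, `"power"`, `"fractional"`), `theta`
#'   (initial value) and `ref` (centering value).
#' @param estimated character vector of parameter names the fitter varies.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(size_metric = "NFM", maturation = TRUE,
                       gst_covariate = TRUE, iov = TRUE,
                       etas = c("cl", "vc", "vp"),
                       occ_breaks = c(6, 36, 66),
                       covariates = list(),
                       estimated = c("theta_cl", "theta_vc", "theta_q",
                                     "theta_vp", "omega_cl", "omega_vc",
                                     "omega_vp", "pi_cl", "sigma_prop",
                                     "sigma_add")) {
  size_metric <- match.arg(size_metric, c("WT", "BSA", "FFM", "NFM"))
  etas <- match.arg(etas, c("cl", "vc", "vp"), several.ok = TRUE)
  if (!iov) estimated <- setdiff(estimated, "pi_cl")
  for (e in c("cl", "vc", "vp"))
    if (!(e %in% etas))
      estimated <- setdiff(estimated, paste0("omega_", e))
  spec <- list(size_metric = size_metric, maturation = maturation,
               gst_covariate = gst_covariate, iov = iov, etas = etas,
               occ_breaks = occ_breaks, covariates = covariates,
               estimated = estimated)
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$size_metric, "allometry |",
      if (x$maturation) "maturation" else "no maturation", "|",
      if (x$gst_covariate) "GST on S_GSH" else "no GST", "|",
      "etas:", paste(x$etas, collapse = ","),
      if (x$iov) sprintf("| IOV (%d occasions)", length(x$occ_breaks) + 1)
      else "| no IOV", "\n")
  if (length(x$covariates))
    for (tm in x$covariates)
      cat(sprintf("  + %s on %s (%s, theta=%.3g, ref=%.3g)\n",
                  tm$cov, tm$param, tm$form, tm$theta, tm$ref))
  cat("  estimated:", paste(x$estimated, collapse = ", "), "\n")
  invisible(x)
}

# names of extra covariate thetas carried by a spec (estimated on the
# natural scale since they may be negative)
covariate_theta_names <- function(spec) {
  if (!length(spec$covariates)) return(character())
  vapply(seq_along(spec$covariates), function(i) {
    tm <- spec$covariates[[i]]
    if (!is.null(tm$name)) tm$name
    else paste0("beta_", tm$param, "_", tolower(tm$cov))
  }, character(1))
}
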