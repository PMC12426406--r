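#' Fat-free mass from height, weight and sex
#'
#' Height-weight fat-free mass (Janmahasatian form):
#' \deqn{FFM = \frac{42.92\,H^2\,W}{30.93\,H^2 + W}} for males and
#' \deqn{FFM = \frac{37.99\,H^2\,W}{35.98\,H^2 + W}} for females,
#' with height \eqn{H} in metres and weight \eqn{W} in kg. For severely
#' underweight height/weight combinations the raw formula can exceed body
#' weight; the result is capped at `wt` so that `0 < FFM <= WT` always holds.
#'
#' @param wt body weight (kg), positive.
#' @param ht height (cm), positive.
#' @param sex `"male"` or `"female"` (recycled).
#' @return fat-free mass (kg).
#' @examples
#' compute_ffm(70, 176, "male") # ~56.1 kg reference adult
#' @export
compute_ffm <- function(wt, ht, sex = "male") {
  if (any(!is.finite(wt)) || any(wt <= 0)) stop("wt must be positive")
  if (any(!is.finite(ht)) || any(ht <= 0)) stop("ht must be positive")
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  n <- max(length(wt), length(ht), length(sex))
  wt <- rep_len(wt, n); ht <- rep_len(ht, n); sex <- rep_len(sex, n)
  h2 <- (ht / 100)^2
  ffm <- ifelse(sex == "male",
                42.92 * h2 * wt / (30.93 * h2 + wt),
                37.99 * h2 * wt / (35.98 * h2 + wt))
  pmin(ffm, wt)
}

#' Body surface area (Mosteller)
#'
#' @param wt weight (kg).
#' @param ht height (cm).
#' @return BSA in m^2.
#' @export
compute_bsa <- function(wt, ht) {
  if (any(wt <= 0) || any(ht <= 0)) stop("wt and ht must be positive")
  sqrt(ht * wt / 3600)
}

#' Normal fat mass
#'
#' NFM partitions weight into fat-free mass and a parameter-specific
#' fraction of the fat mass: `NFM = FFM + ffat * (WT - FFM)`. With
#' `ffat = 0` NFM collapses to FFM; with `ffat = 1` it equals total weight.
#'
#' @param ffm fat-free mass (kg), `0 < ffm <= wt`.
#' @param wt body weight (kg).
#' @param ffat fat-mass fraction (dimensionless, >= 0).
#' @return normal fat mass (kg).
#' @export
compute_nfm <- function(ffm, wt, ffat) {
  if (any(ffm <= 0) || any(wt <= 0)) stop("ffm and wt must be positive")
  if (any(ffm > wt + 1e-9)) stop("ffm must not exceed wt")
  if (any(ffat < 0)) stop("ffat must be non-negative")
  ffm + ffat * (wt - ffm)
}

#' Sigmoid maturation fraction of adult clearance
#'
#' Fraction of the adult clearance attained at a given postmenstrual age:
#' \deqn{F_{mat} = \frac{1}{1 + (PMA/TM_{50})^{-Hill}}}
#' `tm50` is the PMA (weeks) at which 50% of the adult value is reached and
#' `hill` sets the steepness. Strictly increasing in `pma` with asymptote 1.
#'
#' @param pma postmenstrual age (weeks), positive.
#' @param tm50 half-maturation PMA (weeks), positive.
#' @param hill sigmoidicity (dimensionless), positive.
#' @return maturation fraction in (0, 1).
#' @export
maturation_fraction <- function(pma, tm50, hill) {
  if (any(pma <= 0) || any(tm50 <= 0) || any(hill <= 0))
    stop("pma, tm50 and hill must be positive")
  1 / (1 + (pma / tm50)^(-hill))
}

#' GST-activity multiplier on the GSH depletion scale
#'
#' Exponential covariate effect of measured glutathione S-transferase
#' activity on the depletion scale factor, centred at a reference activity:
#' `exp(theta_gst * (gst / gst_ref - 1))`. Equal to 1 at the reference and
#' monotone increasing in `gst` for positive slope.
#'
#' @param gst GST activity (nmol/min/mL), non-negative.
#' @param theta_gst dimensionless slope.
#' @param gst_ref reference activity (nmol/min/mL), positive; default is the
#'   cohort median 9.2.
#' @return positive multiplier.
#' @export
gst_multiplier <- function(gst, theta_gst, gst_ref = 9.2) {
  if (any(gst < 0)) stop("gst must be non-negative")
  if (gst_ref <= 0) stop("gst_ref must be positive")
  exp(theta_gst * (gst / gst_ref - 1))
}

#' Postmenstrual age from gestational and postnatal age
#'
#' @param gestational_age weeks.
#' @param postnatal_age years (1 year = 52.1775 weeks).
#' @return PMA in weeks.
#' @export
compute_pma <- function(gestational_age, postnatal_age) {
  gestational_age + postnatal_age * 52.1775
}

#' Subject covariate record
#'
#' Bundles the demographics and GST activity that drive the covariate model.
#' FFM and PMA are computed when not supplied.
#'
#' @param id subject label.
#' @param sex `"male"` or `"female"`.
#' @param postnatal_age years.
#' @param gestational_age weeks (default 40).
#' @param wt weight (kg).
#' @param ht height (cm).
#' @param ffm fat-free mass (kg); computed from `wt`, `ht`, `sex` if `NULL`.
#' @param gst GST activity (nmol/min/mL).
#' @param comedication character vector of concomitant-drug labels.
#' @return object of class `subject_covariates`.
#' @export
subject_covariates <- function(id, sex = "male", postnatal_age, wt, ht = NULL,
                               gestational_age = 40, ffm = NULL, gst = 9.2,
                               comedication = character()) {
  sex <- match.arg(sex, c("male", "female"))
  if (wt <= 0) stop("wt must be positive")
  if (postnatal_age < 0) stop("postnatal_age must be non-negative")
  if (gst < 0) stop("gst must be non-negative")
  if (is.null(ffm)) {
    if (is.null(ht)) stop("supply either ffm or ht")
    ffm <- compute_ffm(wt, ht, sex)
  }
  if (ffm <= 0 || ffm > wt + 1e-9) stop("ffm must satisfy 0 < ffm <= wt")
  out <- list(id = id, sex = sex, postnatal_age = postnatal_age,
              gestational_age = gestational_age,
              pma = compute_pma(gestational_age, postnatal_age),
              wt = wt, ht = ht, ffm = ffm, gst = gst,
              comedication = comedication)
  class(out) <- "subject_covariates"
  out
}

#' @export
print.subject_covariates <- function(x, ...) {
  cat(sprintf("<subject %s> %s, age %.2f y (PMA %.1f wk), WT %.1f kg, FFM %.2f kg, GST %.2f nmol/min/mL\n",
              x$id, x$sex, x$postnatal_age, x$pma, x$wt, x$ffm, x$gst))
  invisible(x)
}
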