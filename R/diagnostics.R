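# eta/epsilon shrinkage from the empirical Bayes estimates held on a fit
shrinkage_internal <- function(fitres) {
  lay <- fitres$layout
  eb <- do.call(rbind, lapply(fitres$ebe, function(b)
    if (length(b)) b else rep(NA_real_, lay$n_b)))
  eta <- c()
  if (lay$n_eta > 0) {
    for (k in seq_len(lay$n_eta)) {
      om <- sqrt(lay$omega2[k])
      eta[paste0("eta_", lay$eta_names[k])] <-
        100 * (1 - stats::sd(eb[, k]) / om)
    }
  }
  if (lay$kap_off >= 0) {
    kap <- as.vector(eb[, (lay$n_eta + 1):lay$n_b])
    eta["kappa_cl"] <- 100 * (1 - stats::sd(kap) / sqrt(lay$omega2[lay$n_b]))
  }
  # IWRES = (DV - IPRED) / sqrt(v(IPRED)) over all observations
  iw <- c()
  subs <- split_subjects(fitres$dataset, fitres$spec$occ_breaks)
  for (i in seq_along(subs)) {
    d <- fitres$subject_details[[i]]
    if (is.null(d$f)) next
    iw <- c(iw, (subs[[i]]$dv - d$f) / sqrt(d$v))
  }
  eps <- if (length(iw) > 1) 100 * (1 - stats::sd(iw)) else NA_real_
  list(eta = eta, eps = eps)
}

#' Shrinkage diagnostics
#'
#' Eta-shrinkage per random effect, `100 * (1 - SD(EBE)/omega)`, and
#' epsilon-shrinkage `100 * (1 - SD(IWRES))`. Values near 0 mean the data
#' are informative about the individual effects; values above ~30% flag
#' EBE-based diagnostics as unreliable. Effects with zero variance are
#' reported as `NA`.
#'
#' @param fitres a [fit()] result.
#' @return list with `eta` (named vector, percent) and `eps` (percent).
#' @export
shrinkage <- function(fitres) {
  stopifnot(inherits(fitres, "fit_result"))
  list(eta = fitres$eta_shrinkage, eps = fitres$eps_shrinkage)
}

#' Conditional weighted residuals
#'
#' FOCE-linearised residuals: with prediction sensitivities `G` at the
#' empirical Bayes mode `b`, the marginal moments are
#' `E = f(b) - G b` and `Cov = G Omega G' + diag(v)`, and
#' `CWRES = Cov^{-1/2} (DV - E)`. On data simulated from the fitted model
#' they are approximately standard normal.
#'
#' @param fitres a [fit()] result.
#' @return data.frame with `ID`, `TIME`, `DV`, `CWRES`.
#' @export
cwres <- function(fitres) {
  stopifnot(inherits(fitres, "fit_result"))
  subs <- split_subjects(fitres$dataset, fitres$spec$occ_breaks)
  lay <- fitres$layout
  out <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    d <- fitres$subject_details[[i]]
    s <- subs[[i]]
    if (lay$n_b == 0 || is.null(d$G)) {
      w <- (s$dv - d$f) / sqrt(d$v)
    } else {
      E <- d$f - as.vector(d$G %*% d$b)
      V <- d$G %*% diag(lay$omega2, lay$n_b) %*% t(d$G) + diag(d$v,
                                                               length(d$v))
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) {
        w <- rep(NA_real_, length(s$dv))  # singular covariance: flagged
      } else {
        w <- backsolve(ch, s$dv - E, transpose = TRUE)
      }
    }
    out[[i]] <- data.frame(ID = s$id, TIME = s$obs_times, DV = s$dv,
                           CWRES = as.vector(w))
  }
  do.call(rbind, out)
}

#' Goodness-of-fit table
#'
#' One row per observation with the population prediction (`PRED`, all
#' random effects zero), the individual prediction (`IPRED`, at the
#' empirical Bayes mode), `IWRES` and `CWRES` — the tabular basis of the
#' usual GOF panels.
#'
#' @param fitres a [fit()] result.
#' @return data.frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `IWRES`,
#'   `CWRES`.
#' @export
gof_tables <- function(fitres) {
  stopifnot(inherits(fitres, "fit_result"))
  subs <- split_subjects(fitres$dataset, fitres$spec$occ_breaks)
  if (!length(subs))
    return(data.frame(ID = character(), TIME = numeric(), DV = numeric(),
                      PRED = numeric(), IPRED = numeric(), IWRES = numeric(),
                      CWRES = numeric()))
  cw <- cwres(fitres)
  lay <- fitres$layout
  pop <- fitres$estimates
  out <- vector("list", length(subs))
  ctl <- fitres$control
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    d <- fitres$subject_details[[i]]
    ind0 <- d$ind0
    pred0 <- cpp_subject_pred(rep(0, max(lay$n_b, 0)), s$obs_times,
                              s$d_start, s$d_dur, s$d_amt, ind0$cl_i,
                              ind0$vc_i, ind0$q_i, ind0$vp_i, ind0$s_gsh_i,
                              pop$k_gsh, lay$eta_idx, lay$kap_off,
                              fitres$spec$occ_breaks, ctl$rtol, ctl$atol)
    ipred <- if (!is.null(d$f)) d$f else pred0
    v <- if (!is.null(d$v)) d$v else
      (pred0 * pop$sigma_prop)^2 + pop$sigma_add^2
    out[[i]] <- data.frame(ID = s$id, TIME = s$obs_times, DV = s$dv,
                           PRED = pred0, IPRED = ipred,
                           IWRES = (s$dv - ipred) / sqrt(v))
  }
  res <- do.call(rbind, out)
  res$CWRES <- cw$CWRES
  rownames(res) <- NULL
  res
}
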