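#' Population predictions for every observation row
#'
#' Typical-subject (all random effects zero) predictions under the
#' covariate model — the a-priori predictions used for prediction metrics
#' and pcVPC correction.
#'
#' @param dataset a [as_dataset()] event table.
#' @param pop [population_parameters()].
#' @param spec [model_spec()].
#' @param control [fit_control()] (ODE tolerances).
#' @return data.frame `ID`, `TIME`, `DV`, `PRED`.
#' @export
population_predictions <- function(dataset, pop, spec = model_spec(),
                                   control = fit_control()) {
  subs <- split_subjects(dataset, spec$occ_breaks)
  out <- lapply(subs, function(s) {
    ind0 <- individual_parameters(pop, s$cov, c(cl = 0, vc = 0, vp = 0),
                                  0, spec)
    reg <- data.frame(start_time = s$d_start, amount = s$d_amt,
                      duration = s$d_dur)
    prof <- simulate_profile(ind0, reg, obs_times = s$obs_times,
                             k_gsh = pop$k_gsh, rtol = control$rtol,
                             atol = control$atol)
    data.frame(ID = s$id, TIME = s$obs_times, DV = s$dv, PRED = prof$conc)
  })
  do.call(rbind, out)
}

# time since the most recent dose start, per observation row
time_after_dose <- function(dataset) {
  tad <- rep(NA_real_, nrow(dataset))
  for (id in unique(dataset$ID)) {
    sel <- dataset$ID == id
    rows <- dataset[sel, ]
    dose_t <- rows$TIME[rows$EVID == 1]
    # strict inequality: a trough drawn at a dose time belongs to the
    # previous dosing interval
    tad[sel] <- vapply(rows$TIME, function(t) {
      prev <- dose_t[dose_t < t]
      if (!length(prev)) t else t - max(prev)
    }, numeric(1))
  }
  tad
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulated replicates are normalised by the bin-median
#' population prediction (`pc = value * median(PRED_bin) / PRED_i`), binned
#' on time-after-dose by equal-count quantiles, and summarised as the
#' 5th/50th/95th percentiles per bin; the simulation replicates provide a
#' 95% confidence band for each percentile. Covariates are reused from the
#' observed dataset (not re-sampled); residual error is included in the
#' simulated observations.
#'
#' @param dataset a [as_dataset()] event table.
#' @param fitres a [fit()] result or a [population_parameters()] object.
#' @param n_sim number of Monte-Carlo replicates (>= 100).
#' @param bins number of time-after-dose bins.
#' @param seed integer seed.
#' @param spec [model_spec()] (only needed when `fitres` is a bare
#'   parameter set).
#' @param control [fit_control()].
#' @return object of class `vpc_result`: data.frame `table` with, per bin
#'   and percentile, the observed value and its simulated 95% band, plus
#'   `n_sim`.
#' @export
pcvpc <- function(dataset, fitres, n_sim = 2000, bins = 8, seed = 1,
                  spec = model_spec(), control = fit_control()) {
  if (inherits(fitres, "fit_result")) {
    pop <- fitres$estimates; spec <- fitres$spec
  } else pop <- fitres
  if (n_sim < 100) stop("n_sim must be at least 100")
  set.seed(seed)
  subs <- split_subjects(dataset, spec$occ_breaks)
  obs_df <- population_predictions(dataset, pop, spec, control)
  tad_all <- time_after_dose(dataset)
  obs_sel <- dataset$EVID == 0 & dataset$MDV == 0
  obs_df$TAD <- tad_all[obs_sel]
  drop <- obs_df$PRED <= 0
  if (any(drop)) {
    warning(sum(drop), " records with zero population prediction excluded")
    obs_df <- obs_df[!drop, ]
  }
  qs <- unique(stats::quantile(obs_df$TAD, probs = seq(0, 1, length.out =
                                                         bins + 1)))
  obs_df$bin <- cut(obs_df$TAD, qs, include.lowest = TRUE)
  obs_df$bin <- droplevels(obs_df$bin)  # scheduled designs tie heavily
  med_pred <- tapply(obs_df$PRED, obs_df$bin, stats::median)
  obs_df$pc <- obs_df$DV * med_pred[obs_df$bin] / obs_df$PRED
  pct <- c(0.05, 0.5, 0.95)
  obs_stat <- do.call(rbind, lapply(levels(obs_df$bin), function(bl) {
    x <- obs_df$pc[obs_df$bin == bl]
    data.frame(bin = bl, percentile = 100 * pct,
               observed = as.numeric(stats::quantile(x, pct)))
  }))
  # simulate replicates (same design & covariates, new eta/kappa/eps)
  lay <- ranef_layout(pop, spec)
  n_occ <- lay$n_occ
  sim_stats <- array(NA_real_, c(length(levels(obs_df$bin)), 3, n_sim))
  for (r in seq_len(n_sim)) {
    sim_dv <- numeric(nrow(obs_df))
    off <- 0
    for (s in subs) {
      eta <- c(cl = stats::rnorm(1, 0, pop$omega_cl),
               vc = stats::rnorm(1, 0, pop$omega_vc),
               vp = stats::rnorm(1, 0, pop$omega_vp))
      kappa <- if (isTRUE(spec$iov))
        stats::rnorm(n_occ, 0, pop$pi_cl) else rep(0, n_occ)
      ind <- individual_parameters(pop, s$cov, eta, kappa, spec)
      reg <- data.frame(start_time = s$d_start, amount = s$d_amt,
                        duration = s$d_dur)
      prof <- simulate_profile(ind, reg, obs_times = s$obs_times,
                               k_gsh = pop$k_gsh,
                               occ_breaks = spec$occ_breaks,
                               rtol = control$rtol, atol = control$atol)
      y <- apply_residual(prof$conc, pop$sigma_prop, pop$sigma_add)
      keep <- seq_along(y)
      sim_dv[off + keep] <- y
      off <- off + length(y)
    }
    pc_sim <- sim_dv[!drop] * med_pred[obs_df$bin] / obs_df$PRED
    for (b in seq_along(levels(obs_df$bin))) {
      x <- pc_sim[as.integer(obs_df$bin) == b]
      sim_stats[b, , r] <- stats::quantile(x, pct)
    }
  }
  lo <- apply(sim_stats, c(1, 2), stats::quantile, 0.025)
  hi <- apply(sim_stats, c(1, 2), stats::quantile, 0.975)
  md <- apply(sim_stats, c(1, 2), stats::median)
  tab <- obs_stat
  tab$sim_median <- as.vector(t(md))
  tab$lower <- as.vector(t(lo))
  tab$upper <- as.vector(t(hi))
  out <- list(table = tab, n_sim = n_sim, bins = qs)
  class(out) <- "vpc_result"
  out
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("<vpc_result> %d simulations, %d bins\n", x$n_sim,
              length(x$bins) - 1))
  print(x$table, digits = 4)
  invisible(x)
}

#' Nonparametric bootstrap of the model fit
#'
#' Resamples subjects with replacement, refits each replicate, and
#' summarises per-parameter medians and percentile confidence intervals
#' over the converged replicates. A convergence fraction below 50% flags
#' the result unreliable.
#'
#' @param dataset a [as_dataset()] event table (>= 2 subjects).
#' @param spec [model_spec()].
#' @param n_boot number of resampled datasets.
#' @param seed integer seed.
#' @param init [population_parameters()] initial values.
#' @param control [fit_control()].
#' @return object of class `bootstrap_result`: data.frame `table`
#'   (parameter, median, lower 2.5%, upper 97.5%), `convergence_fraction`,
#'   `reliable`.
#' @export
bootstrap <- function(dataset, spec = model_spec(), n_boot = 500, seed = 1,
                      init = population_parameters(),
                      control = fit_control(hessian = FALSE)) {
  ids <- unique(dataset$ID)
  if (length(ids) < 2) stop("bootstrap needs at least 2 subjects")
  set.seed(seed)
  nm <- c(spec$estimated, covariate_theta_names(spec))
  est <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
  ok <- logical(n_boot)
  for (r in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      rows <- dataset[dataset$ID == take[k], , drop = FALSE]
      rows$ID <- sprintf("B%03d", k)
      rows
    })
    ds <- as_dataset(do.call(rbind, pieces))
    ft <- tryCatch(fit(ds, spec, init, control), error = function(e) NULL)
    if (!is.null(ft) && ft$status == "converged") {
      ok[r] <- TRUE
      vals <- c(unlist(ft$estimates[spec$estimated]),
                vapply(ft$spec$covariates, function(tm) tm$theta, numeric(1)))
      est[r, ] <- vals[seq_along(nm)]
    }
  }
  conv <- mean(ok)
  tab <- data.frame(
    parameter = nm,
    median = apply(est[ok, , drop = FALSE], 2, stats::median),
    lower = apply(est[ok, , drop = FALSE], 2, stats::quantile, 0.025),
    upper = apply(est[ok, , drop = FALSE], 2, stats::quantile, 0.975))
  out <- list(table = tab, convergence_fraction = conv,
              reliable = conv >= 0.5, n_boot = n_boot, seed = seed)
  class(out) <- "bootstrap_result"
  if (!out$reliable)
    warning("bootstrap convergence fraction below 50%; result unreliable")
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates, %.0f%% converged%s\n",
              x$n_boot, 100 * x$convergence_fraction,
              if (x$reliable) "" else " (UNRELIABLE)"))
  print(x$table, digits = 4)
  invisible(x)
}

#' Prediction-error metrics
#'
#' Percentage prediction errors `PE% = 100 (pred - obs) / obs` summarised
#' as the median (MDPE, bias), median absolute value (MAPE, precision) and
#' the percentage of |PE%| within 20% (F20) and 30% (F30). Records with
#' non-positive observations are excluded with a warning. All four metrics
#' are invariant to rescaling obs and pred by a common factor.
#'
#' @param obs observed concentrations (mg/L).
#' @param pred predicted concentrations (mg/L), same length.
#' @return named list `mdpe`, `mape`, `f20`, `f30` (all percent).
#' @export
prediction_metrics <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred must match in length")
  bad <- obs <= 0
  if (any(bad)) {
    warning(sum(bad), " records with non-positive observation excluded")
    obs <- obs[!bad]; pred <- pred[!bad]
  }
  pe <- 100 * (pred - obs) / obs
  list(mdpe = stats::median(pe),
       mape = stats::median(abs(pe)),
       f20 = 100 * mean(abs(pe) <= 20),
       f30 = 100 * mean(abs(pe) <= 30))
}
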