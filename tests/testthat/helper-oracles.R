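# Independent oracles, kept free of the package's integration path.

# Analytic two-compartment concentration under superposed constant-rate
# infusions (linear kinetics, i.e. no GSH coupling). Unit bolus response
# C(t) = A e^{-alpha t} + B e^{-beta t}; an infusion of rate R over
# [t0, t0+D] contributes R * (H(t-t0) - H(t-t0-D)) with H the integral of
# the bolus response.
two_cpt_inf_conc <- function(t, cl, vc, q, vp, d_start, d_dur, d_amt) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (vc * (alpha - beta))
  B <- (k21 - beta) / (vc * (alpha - beta))
  H <- function(x) ifelse(x > 0,
                          A / alpha * (1 - exp(-alpha * x)) +
                            B / beta * (1 - exp(-beta * x)), 0)
  conc <- numeric(length(t))
  for (i in seq_along(d_start)) {
    R <- d_amt[i] / d_dur[i]
    conc <- conc + R * (H(t - d_start[i]) - H(t - d_start[i] - d_dur[i]))
  }
  conc
}

# Exact marginal -2 log-likelihood of a one-eta (on CL) linear
# two-compartment subject by adaptive Gauss-Hermite quadrature (nodes
# centred at the mode of the integrand and scaled by its curvature),
# using the analytic concentration, never the package integrator.
gh_neg2ll_one_eta <- function(obs_times, dv, d_start, d_dur, d_amt,
                              cl_base, vc, q, vp, omega, sigma_prop,
                              sigma_add, n_nodes = 31) {
  log_joint <- function(eta) {
    f <- two_cpt_inf_conc(obs_times, cl_base * exp(eta), vc, q, vp,
                          d_start, d_dur, d_amt)
    v <- (f * sigma_prop)^2 + sigma_add^2
    sum(stats::dnorm(dv, f, sqrt(v), log = TRUE)) +
      stats::dnorm(eta, 0, omega, log = TRUE)
  }
  mode <- stats::optimize(log_joint, c(-4, 4), maximum = TRUE)$maximum
  h <- 1e-4
  curv <- -(log_joint(mode + h) - 2 * log_joint(mode) +
              log_joint(mode - h)) / h^2
  s <- 1 / sqrt(max(curv, 1e-8))
  gh <- pracma::gaussHermite(n_nodes)
  lik <- 0
  for (k in seq_len(n_nodes)) {
    eta <- mode + sqrt(2) * s * gh$x[k]
    lik <- lik + gh$w[k] * exp(gh$x[k]^2 + log_joint(eta))
  }
  -2 * (log(lik) + log(sqrt(2) * s))
}

# Closed-form probability that a lognormally distributed cumulative AUC
# falls inside the target window, for dose-over-clearance exposure with
# log-scale SD sigma (valid when the GSH coupling is switched off).
pta_lognormal <- function(total_dose, cl_typ, sigma, lo = 78, hi = 101) {
  m <- log(total_dose / cl_typ)
  100 * (stats::pnorm((log(hi) - m) / sigma) -
           stats::pnorm((log(lo) - m) / sigma))
}
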