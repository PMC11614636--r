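#' Define a synthetic two-arm trial scenario
#'
#' Describes a two-arm trial with parametric OS and PFS marginals per arm,
#' subject-level dependence between PFS and OS, administrative censoring
#' and exponential dropout. Defaults emulate a two-arm first-line
#' immunochemotherapy trial in advanced gastric cancer: ~500 subjects per
#' arm, log-logistic OS/PFS marginals matching the packaged intent-to-treat
#' fits, 36-month administrative cutoff and 1 percent monthly dropout.
#'
#' @param n_per_arm Subjects per arm (>= 10).
#' @param os_intervention,pfs_intervention,os_comparator,pfs_comparator
#'   [surv_spec()] marginals per arm.
#' @param cutoff_months Administrative censoring time (> 0).
#' @param dropout_rate Exponential dropout rate per month (0 disables).
#' @param risk_interval_months Spacing of published number-at-risk tables.
#' @param copula_rho Gaussian-copula correlation between the PFS and OS
#'   uniforms (default 0.6); `PFS <= OS` is additionally enforced by
#'   componentwise minimum.
#' @param seed Random seed.
#' @return A `trial_scenario` object.
#' @export
trial_scenario <- function(
    n_per_arm = 500,
    os_intervention = surv_spec("loglogistic", c(shape = 1.5932, scale = 15.1363)),
    pfs_intervention = surv_spec("loglogistic", c(shape = 1.5899, scale = 7.6197)),
    os_comparator = surv_spec("loglogistic", c(shape = 1.9040, scale = 12.8902)),
    pfs_comparator = surv_spec("loglogistic", c(shape = 1.7759, scale = 6.1872)),
    cutoff_months = 36, dropout_rate = 0.01,
    risk_interval_months = 3, copula_rho = 0.6, seed = 1L) {
  stopifnot(n_per_arm >= 10, cutoff_months > 0, dropout_rate >= 0,
            copula_rho > -1, copula_rho < 1)
  structure(list(n_per_arm = n_per_arm,
                 os_intervention = os_intervention,
                 pfs_intervention = pfs_intervention,
                 os_comparator = os_comparator,
                 pfs_comparator = pfs_comparator,
                 cutoff_months = cutoff_months,
                 dropout_rate = dropout_rate,
                 risk_interval_months = risk_interval_months,
                 copula_rho = copula_rho, seed = seed),
            class = "trial_scenario")
}

.simulate_arm <- function(n, os_spec, pfs_spec, cutoff, dropout, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  u_os <- stats::pnorm(z1)
  u_pfs <- stats::pnorm(z2)
  clip <- function(u) pmin(pmax(u, 1e-12), 1 - 1e-12)
  t_os <- surv_quantile(os_spec, clip(u_os))
  t_pfs <- pmin(surv_quantile(pfs_spec, clip(u_pfs)), t_os)
  cens <- rep(cutoff, n)
  if (dropout > 0) cens <- pmin(cens, stats::rexp(n, rate = dropout))
  os <- data.frame(time = pmin(t_os, cens),
                   event = as.integer(t_os <= cens))
  pfs <- data.frame(time = pmin(t_pfs, cens),
                    event = as.integer(t_pfs <= cens))
  os$time <- pmax(os$time, 1e-6); pfs$time <- pmax(pfs$time, 1e-6)
  list(os = os, pfs = pfs)
}

#' Simulate a synthetic two-arm trial
#'
#' Subject-level `(PFS, OS)` pairs are generated through a Gaussian copula
#' on the marginal inverse CDFs with `PFS <= OS` enforced by componentwise
#' minimum; censoring is the earlier of the administrative cutoff and an
#' independent exponential dropout time. Reproducible under the scenario
#' seed.
#'
#' @param scenario A [trial_scenario()].
#' @return List with elements `intervention` and `comparator`, each a list
#'   of `os` and `pfs` data frames (`time`, `event`).
#' @export
simulate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (scenario$cutoff_months <= 0) stop("infeasible censoring cutoff",
                                        call. = FALSE)
  set.seed(scenario$seed)
  list(
    intervention = .simulate_arm(scenario$n_per_arm,
                                 scenario$os_intervention,
                                 scenario$pfs_intervention,
                                 scenario$cutoff_months,
                                 scenario$dropout_rate,
                                 scenario$copula_rho),
    comparator = .simulate_arm(scenario$n_per_arm,
                               scenario$os_comparator,
                               scenario$pfs_comparator,
                               scenario$cutoff_months,
                               scenario$dropout_rate,
                               scenario$copula_rho))
}

#' Publish a KM curve the way a journal figure would show it
#'
#' Computes the product-limit curve of the IPD, optionally perturbs the
#' survival coordinates with digitization jitter, and attaches a
#' number-at-risk table on a regular grid — producing the kind of input a
#' curve-digitization workflow yields.
#'
#' @param ipd Data frame `time`, `event`.
#' @param interval Risk-table spacing in months.
#' @param jitter_sd Standard deviation of the digitization noise added to
#'   the survival coordinates (default 0.002; 0 for exact coordinates).
#' @param seed Seed for the jitter.
#' @return A [km_curve()].
#' @export
publish_km <- function(ipd, interval = 3, jitter_sd = 0.002, seed = 1L) {
  curve <- km_estimate(ipd, risk_interval = interval)
  if (jitter_sd > 0) {
    set.seed(seed)
    s <- curve$coords$survival
    noise <- stats::rnorm(length(s) - 1, sd = jitter_sd)
    s[-1] <- pmin(1, pmax(0, s[-1] + noise))
    # published figures are themselves monotone; digitization noise moves
    # coordinates but a digitizer walks the curve left to right
    curve$coords$survival <- cummin(s)
  }
  curve
}
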