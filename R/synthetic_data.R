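#' Simulation specification for trial-like synthetic data
#'
#' Defines a two-arm trial whose true survival laws are known, plus the
#' digitization process that turns its Kaplan-Meier curves into the
#' (time, survival) coordinates and numbers-at-risk a graph digitizer
#' would yield. Defaults mirror the study's conditions: the
#' chemotherapy-arm Weibull laws, 2:1 randomization (312 vs 154), hazard
#' ratios 0.71 (OS) and 0.56 (PFS), and rounding-only digitization noise.
#'
#' @param true_os,true_pfs Chemotherapy-arm [weibull_params()].
#' @param hr_os,hr_pfs Hazard ratios deriving the intervention arm.
#' @param n_cct,n_pct Arm sizes.
#' @param admin_censor_time Administrative censoring time, months.
#' @param dropout_rate Exponential dropout rate per month (0 = none).
#' @param digitize_grid Digitization grid step, months (default 0.1: a
#'   two-year time axis read off at roughly pixel resolution, as dense
#'   point extraction in digitizer software produces; coarser grids bias
#'   reconstructed event times late by up to one grid step).
#' @param coord_decimals Decimals the digitized survival coordinates are
#'   rounded to.
#' @param seed RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(true_os = weibull_params(0.030040, 1.213530),
                     true_pfs = weibull_params(0.061800, 1.388300),
                     hr_os = 0.71, hr_pfs = 0.56,
                     n_cct = 312, n_pct = 154,
                     admin_censor_time = 24, dropout_rate = 0,
                     digitize_grid = 0.1, coord_decimals = 3,
                     seed = 20230726) {
  if (n_pct < 10 || n_cct < 10) stop("arm sizes must be at least 10")
  if (admin_censor_time <= 0) stop("'admin_censor_time' must be positive")
  if (digitize_grid <= 0) stop("'digitize_grid' must be positive")
  structure(list(true_os = true_os, true_pfs = true_pfs,
                 hr_os = hr_os, hr_pfs = hr_pfs,
                 n_cct = n_cct, n_pct = n_pct,
                 admin_censor_time = admin_censor_time,
                 dropout_rate = dropout_rate,
                 digitize_grid = digitize_grid,
                 coord_decimals = coord_decimals, seed = seed),
            class = "sim_spec")
}

#' Simulate per-patient time-to-event records
#'
#' Event times by inverse-transform sampling of the Weibull law
#' \eqn{T = (-\ln U/\lambda)^{1/\gamma}}, independent exponential dropout,
#' and administrative censoring.
#'
#' @param params True [weibull_params()].
#' @param n Number of patients.
#' @param admin_censor_time Administrative censoring time, months
#'   (`Inf` = none).
#' @param dropout_rate Exponential dropout rate per month.
#' @param arm Arm label.
#' @return A [pseudo_ipd()].
#' @export
simulate_ipd <- function(params, n, admin_censor_time = Inf,
                         dropout_rate = 0, arm = "") {
  stopifnot(inherits(params, "weibull_params"))
  u <- stats::runif(n)
  event_time <- (-log(u) / params$scale)^(1 / params$shape)
  cens_time <- if (dropout_rate > 0)
    pmin(stats::rexp(n, dropout_rate), admin_censor_time)
  else rep(admin_censor_time, n)
  pseudo_ipd(pmin(event_time, cens_time),
             as.integer(event_time <= cens_time), arm = arm)
}

#' Simulate a full two-arm trial
#'
#' @param spec A [sim_spec()]. The RNG is seeded from `spec$seed`, so the
#'   same specification always yields the same datasets.
#' @return Nested list: `$pct$os`, `$pct$pfs`, `$cct$os`, `$cct$pfs`, each
#'   a [pseudo_ipd()].
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  sim_arm <- function(os, pfs, n, arm) list(
    os = simulate_ipd(os, n, spec$admin_censor_time, spec$dropout_rate,
                      arm = arm),
    pfs = simulate_ipd(pfs, n, spec$admin_censor_time, spec$dropout_rate,
                       arm = arm))
  list(pct = sim_arm(spec$true_os, spec$true_pfs, spec$n_pct, "PCT"),
       cct = sim_arm(scale_by_hr(spec$true_os, spec$hr_os),
                     scale_by_hr(spec$true_pfs, spec$hr_pfs),
                     spec$n_cct, "CCT"))
}

#' Emulate graph digitization of a Kaplan-Meier plot
#'
#' Computes the Kaplan-Meier estimate of the simulated records, samples it
#' on a regular time grid, rounds the survival coordinates to
#' `coord_decimals` (the only digitization noise modelled by default), and
#' tabulates the true numbers at risk at the grid times.
#'
#' @param ipd A [pseudo_ipd()].
#' @param spec A [sim_spec()] supplying `digitize_grid` and
#'   `coord_decimals`.
#' @return List with a `curve` ([digitized_curve()]) and a `risk`
#'   ([risk_table()]).
#' @export
digitize <- function(ipd, spec) {
  stopifnot(inherits(ipd, "pseudo_ipd"), inherits(spec, "sim_spec"))
  if (spec$digitize_grid >= spec$admin_censor_time)
    stop("digitization grid is coarser than the follow-up period")
  t_max <- min(max(ipd$time), spec$admin_censor_time)
  grid <- seq(0, t_max, by = spec$digitize_grid)
  if (max(grid) < t_max) grid <- c(grid, t_max)
  km <- km_estimate(ipd)
  surv <- round(curve_survival_at(km, grid), spec$coord_decimals)
  n_risk <- vapply(grid, function(tt) sum(ipd$time >= tt), numeric(1))
  list(curve = digitized_curve(grid, surv, arm = attr(ipd, "arm")),
       risk = risk_table(grid, n_risk))
}
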