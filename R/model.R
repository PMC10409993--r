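#' Base-case model parameters
#'
#' The full flat parameter set of the analysis: the chemotherapy-arm
#' Weibull survival laws (monthly time scale), the trial hazard ratios
#' used to derive the cemiplimab-arm laws, and every economic input.
#' The sensitivity analyses operate on this flat list by name.
#'
#' @return Named list of parameter values.
#' @export
base_params <- function() {
  list(
    wb_os_pct_scale = 0.030040, wb_os_pct_shape = 1.213530,
    wb_pfs_pct_scale = 0.061800, wb_pfs_pct_shape = 1.388300,
    hr_os = 0.71, hr_pfs = 0.56,
    cost_carboplatin = 3.93, cost_cisplatin = 11.25,
    cost_cemiplimab = 1521.38, cost_pemetrexed = 6.51,
    cost_paclitaxel = 33.68,
    cost_neutropenia = 82.32, cost_anemia = 496.80,
    cost_followup = 92.69, cost_end_of_life = 2665.11, cost_bsc = 365.51,
    inc_anemia_cct = 0.099, inc_neutropenia_cct = 0.058,
    inc_anemia_pct = 0.065, inc_neutropenia_pct = 0.059,
    utility_pfs = 0.804, utility_pd = 0.321,
    disutility_neutropenia = 0.20, disutility_anemia = 0.073,
    bsa = 1.72, crcl = 70, discount_rate = 0.05,
    mix_cct_pem_carbo = 0.369, mix_cct_pem_cis = 0.083,
    mix_cct_pac_carbo = 0.494, mix_cct_pac_cis = 0.054,
    mix_pct_pem_carbo = 0.299, mix_pct_pem_cis = 0.104,
    mix_pct_pac_carbo = 0.532, mix_pct_pac_cis = 0.065)
}

# Assemble economic_inputs from the flat parameter list; each arm's
# regimen mix is renormalized so independently perturbed proportions
# remain a valid mix.
params_to_inputs <- function(p) {
  norm <- function(x) x / sum(x)
  economic_inputs(
    unit_costs = c(carboplatin = p$cost_carboplatin,
                   cisplatin = p$cost_cisplatin,
                   cemiplimab = p$cost_cemiplimab,
                   pemetrexed = p$cost_pemetrexed,
                   paclitaxel = p$cost_paclitaxel),
    care_costs = c(followup_per_cycle = p$cost_followup,
                   bsc_per_cycle = p$cost_bsc,
                   end_of_life = p$cost_end_of_life,
                   anemia = p$cost_anemia,
                   neutropenia = p$cost_neutropenia),
    utilities = c(pfs = p$utility_pfs, pd = p$utility_pd),
    disutilities = c(neutropenia = p$disutility_neutropenia,
                     anemia = p$disutility_anemia),
    teae_incidence = list(
      CCT = c(anemia = p$inc_anemia_cct,
              neutropenia = p$inc_neutropenia_cct),
      PCT = c(anemia = p$inc_anemia_pct,
              neutropenia = p$inc_neutropenia_pct)),
    bsa = p$bsa, crcl = p$crcl,
    regimen_mix = list(
      CCT = norm(c(pem_carbo = p$mix_cct_pem_carbo,
                   pem_cis = p$mix_cct_pem_cis,
                   pac_carbo = p$mix_cct_pac_carbo,
                   pac_cis = p$mix_cct_pac_cis)),
      PCT = norm(c(pem_carbo = p$mix_pct_pem_carbo,
                   pem_cis = p$mix_pct_pem_cis,
                   pac_carbo = p$mix_pct_pac_carbo,
                   pac_cis = p$mix_pct_pac_cis))))
}

#' Evaluate the full cost-effectiveness model
#'
#' Builds both strategies' survival laws (the cemiplimab arm by
#' proportional-hazards scaling of the chemotherapy arm), applies the
#' horizon rule to the slower-dying cemiplimab arm, runs both arms on that
#' common cycle grid, accrues costs and QALYs, and returns the incremental
#' result.
#'
#' @param params Flat parameter list as from [base_params()]; any subset
#'   may be overridden via `overrides`.
#' @param settings A [model_settings()]; its `discount_rate` is taken from
#'   `params$discount_rate`.
#' @param overrides Named list/vector of parameter overrides.
#' @return A [compute_icer()] result, with the per-arm [accrue()] totals
#'   attached as attributes `"cct"` and `"pct"`.
#' @examples
#' res <- evaluate_ce()
#' res$incremental$icer
#' @export
evaluate_ce <- function(params = base_params(),
                        settings = model_settings(), overrides = NULL) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(overrides)] <- overrides
  }
  settings$discount_rate <- params$discount_rate
  os_pct <- weibull_params(params$wb_os_pct_scale, params$wb_os_pct_shape)
  pfs_pct <- weibull_params(params$wb_pfs_pct_scale, params$wb_pfs_pct_shape)
  os_cct <- scale_by_hr(os_pct, params$hr_os)
  pfs_cct <- scale_by_hr(pfs_pct, params$hr_pfs)
  # Common grid: horizon governed by the arm that dies slower.
  slower <- if (survival_at(os_cct, 60) >= survival_at(os_pct, 60))
    os_cct else os_pct
  n_cycles <- horizon_cycles(slower, settings)
  inputs <- params_to_inputs(params)
  tr_cct <- build_trace(os_cct, pfs_cct, settings, n_cycles = n_cycles)
  tr_pct <- build_trace(os_pct, pfs_pct, settings, n_cycles = n_cycles)
  cct <- accrue(tr_cct, strategy_definition("CCT"), inputs, settings)
  pct <- accrue(tr_pct, strategy_definition("PCT"), inputs, settings)
  res <- compute_icer(cct, pct)
  attr(res, "cct") <- cct
  attr(res, "pct") <- pct
  attr(res, "n_cycles") <- n_cycles
  res
}
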