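#' Economic model inputs
#'
#' All unit costs (2022 US dollars), utilities, adverse-event parameters,
#' dosing constants and per-arm chemotherapy regimen mixes. Defaults are
#' the base-case values of the analysis: national tender drug prices, the
#' cemiplimab price set by per-cycle parity with pembrolizumab
#' (2662.41 x 200/350 = 1521.38 USD per 100 mg), literature-based care
#' costs and health-state utilities, and trial-reported grade >=3
#' treatment-emergent adverse-event (TEAE) incidences and regimen
#' proportions.
#'
#' @param unit_costs USD per 100 mg for each drug.
#' @param care_costs USD: routine follow-up per cycle (applied to the
#'   progression-free state), best supportive care per cycle (progressed
#'   state), one-time end-of-life cost (per newly dead), and per-episode
#'   TEAE management costs.
#' @param utilities Health-state utilities for progression-free and
#'   progressed disease.
#' @param disutilities One-cycle utility decrements per TEAE episode.
#' @param teae_incidence Per-arm incidences of grade >=3 anemia and
#'   neutropenia (incidence > 5%).
#' @param bsa Body surface area, m^2.
#' @param crcl Creatinine clearance, ml/min (for the Calvert carboplatin
#'   dose `AUC * (CrCl + 25)` mg).
#' @param regimen_mix Per-arm proportions over the four chemotherapy
#'   backbones; each arm must sum to 1 (+/- 0.001).
#' @param dosing Dose constants: pemetrexed 500 mg/m^2, paclitaxel
#'   200 mg/m^2, cisplatin 75 mg/m^2, carboplatin AUC 5, cemiplimab flat
#'   350 mg.
#' @return An object of class `economic_inputs`.
#' @export
economic_inputs <- function(
    unit_costs = c(carboplatin = 3.93, cisplatin = 11.25,
                   cemiplimab = 1521.38, pemetrexed = 6.51,
                   paclitaxel = 33.68),
    care_costs = c(followup_per_cycle = 92.69, bsc_per_cycle = 365.51,
                   end_of_life = 2665.11, anemia = 496.80,
                   neutropenia = 82.32),
    utilities = c(pfs = 0.804, pd = 0.321),
    disutilities = c(neutropenia = 0.20, anemia = 0.073),
    teae_incidence = list(CCT = c(anemia = 0.099, neutropenia = 0.058),
                          PCT = c(anemia = 0.065, neutropenia = 0.059)),
    bsa = 1.72, crcl = 70,
    regimen_mix = list(
      CCT = c(pem_carbo = 0.369, pem_cis = 0.083,
              pac_carbo = 0.494, pac_cis = 0.054),
      PCT = c(pem_carbo = 0.299, pem_cis = 0.104,
              pac_carbo = 0.532, pac_cis = 0.065)),
    dosing = c(pemetrexed_mg_m2 = 500, paclitaxel_mg_m2 = 200,
               cisplatin_mg_m2 = 75, carboplatin_auc = 5,
               cemiplimab_mg = 350)) {
  if (any(unit_costs < 0) || any(care_costs < 0)) stop("costs must be >= 0")
  if (any(utilities < 0 | utilities > 1)) stop("utilities must lie in [0, 1]")
  for (arm in names(regimen_mix)) {
    if (abs(sum(regimen_mix[[arm]]) - 1) > 0.001)
      stop("regimen mix for arm ", arm, " must sum to 1 (+/- 0.001)")
    if (!setequal(names(regimen_mix[[arm]]),
                  c("pem_carbo", "pem_cis", "pac_carbo", "pac_cis")))
      stop("unknown regimen key in arm ", arm)
  }
  structure(list(unit_costs = unit_costs, care_costs = care_costs,
                 utilities = utilities, disutilities = disutilities,
                 teae_incidence = teae_incidence, bsa = bsa, crcl = crcl,
                 regimen_mix = regimen_mix, dosing = dosing),
            class = "economic_inputs")
}

#' Treatment strategy definition
#'
#' Both arms receive up to four cycles of platinum-doublet chemotherapy;
#' patients on a pemetrexed-containing backbone continue pemetrexed
#' maintenance while progression-free. The cemiplimab arm additionally
#' receives 350 mg every cycle for up to 108 weeks (36 cycles of 21 days).
#' Progressed patients receive best supportive care only.
#'
#' @param arm `"CCT"` (cemiplimab + chemotherapy) or `"PCT"`
#'   (placebo + chemotherapy).
#' @param chemo_cycles Number of induction chemotherapy cycles (default 4).
#' @param cemiplimab_max_cycles Cap on cemiplimab cycles (default 36;
#'   36 x 21 days = 108 weeks).
#' @param maintenance_max_cycles Cap on pemetrexed maintenance (default
#'   `Inf`: maintenance continues while progression-free).
#' @return An object of class `strategy_definition`.
#' @export
strategy_definition <- function(arm = c("CCT", "PCT"), chemo_cycles = 4,
                                cemiplimab_max_cycles = 36,
                                maintenance_max_cycles = Inf) {
  arm <- match.arg(arm)
  structure(list(arm = arm, chemo_cycles = chemo_cycles,
                 cemiplimab_max_cycles = cemiplimab_max_cycles,
                 maintenance_max_cycles = maintenance_max_cycles),
            class = "strategy_definition")
}

# mg dispensed per cycle for each backbone component; per-mg price is
# unit_cost / 100 (prices are quoted per 100 mg), no vial rounding.
.chemo_cycle_cost <- function(inputs) {
  uc <- inputs$unit_costs / 100
  d <- inputs$dosing
  pem <- d[["pemetrexed_mg_m2"]] * inputs$bsa * uc[["pemetrexed"]]
  pac <- d[["paclitaxel_mg_m2"]] * inputs$bsa * uc[["paclitaxel"]]
  cis <- d[["cisplatin_mg_m2"]] * inputs$bsa * uc[["cisplatin"]]
  carbo <- d[["carboplatin_auc"]] * (inputs$crcl + 25) * uc[["carboplatin"]]
  c(pem_carbo = pem + carbo, pem_cis = pem + cis,
    pac_carbo = pac + carbo, pac_cis = pac + cis,
    pem_only = pem)
}

.cemiplimab_cycle_cost <- function(inputs) {
  inputs$dosing[["cemiplimab_mg"]] * inputs$unit_costs[["cemiplimab"]] / 100
}

#' Per-cycle drug cost while progression-free
#'
#' Cycles 1 to `chemo_cycles`: regimen-mix-weighted chemotherapy backbone
#' cost (pemetrexed 500 mg/m^2 x BSA; paclitaxel 200 mg/m^2 x BSA;
#' cisplatin 75 mg/m^2 x BSA; carboplatin by the Calvert formula
#' `AUC x (CrCl + 25)` mg), plus cemiplimab 350 mg in the CCT arm. Later
#' cycles: pemetrexed maintenance weighted by the pemetrexed-backbone
#' fraction, plus cemiplimab in the CCT arm up to its cycle cap.
#'
#' @param strategy A [strategy_definition()].
#' @param inputs An [economic_inputs()].
#' @param cycle_index Cycle number(s), starting at 1.
#' @return Numeric vector of USD per cycle (per fully progression-free
#'   patient), with the cemiplimab component attached as attribute
#'   `"cemiplimab"`.
#' @export
drug_cost_per_cycle <- function(strategy, inputs, cycle_index) {
  stopifnot(inherits(strategy, "strategy_definition"),
            inherits(inputs, "economic_inputs"))
  if (any(cycle_index < 1)) stop("'cycle_index' starts at 1")
  mix <- inputs$regimen_mix[[strategy$arm]]
  cyc <- .chemo_cycle_cost(inputs)
  induction <- sum(mix * cyc[names(mix)])
  pem_frac <- sum(mix[c("pem_carbo", "pem_cis")])
  maint <- pem_frac * cyc[["pem_only"]]
  chemo <- ifelse(cycle_index <= strategy$chemo_cycles, induction,
                  ifelse(cycle_index - strategy$chemo_cycles <=
                           strategy$maintenance_max_cycles, maint, 0))
  cemi <- if (strategy$arm == "CCT")
    ifelse(cycle_index <= strategy$cemiplimab_max_cycles,
           .cemiplimab_cycle_cost(inputs), 0)
  else rep(0, length(cycle_index))
  structure(chemo + cemi, cemiplimab = cemi)
}

#' Accrue costs, life-years and QALYs over a cohort trace
#'
#' Per cycle (occupancy evaluated at cycle end, or averaged over the cycle
#' when `settings$half_cycle`): progression-free occupancy carries the
#' drug cost and routine follow-up; progressed occupancy carries best
#' supportive care; the newly dead carry the one-time end-of-life cost.
#' QALYs accrue as occupancy x state utility x cycle length in years.
#' One-time at cycle 1: incidence-weighted TEAE management costs and
#' one-cycle disutility decrements. Every cash flow and QALY is discounted
#' at its cycle's end time.
#'
#' @param trace A [build_trace()] result.
#' @param strategy A [strategy_definition()]; its arm selects the regimen
#'   mix and TEAE incidences.
#' @param inputs An [economic_inputs()].
#' @param settings The [model_settings()] used to build the trace.
#' @return An object of class `arm_totals`: `total_cost`, `total_qaly`,
#'   `total_ly` (discounted), `total_ly_undisc`, and a `components` cost
#'   breakdown (cemiplimab, chemo, followup, bsc, end_of_life, teae).
#' @export
accrue <- function(trace, strategy, inputs, settings = model_settings()) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(strategy, "strategy_definition"),
            inherits(inputs, "economic_inputs"))
  n <- nrow(trace) - 1L
  empty <- list(total_cost = 0, total_qaly = 0, total_ly = 0,
                total_ly_undisc = 0,
                components = c(cemiplimab = 0, chemo = 0, followup = 0,
                               bsc = 0, end_of_life = 0, teae = 0),
                arm = strategy$arm)
  if (n < 1L) return(structure(empty, class = "arm_totals"))
  cyc <- seq_len(n)
  cycle_years <- settings$cycle_length_days / DAYS_PER_YEAR
  disc <- discount_factor(settings$discount_rate,
                          cyc * settings$cycle_length_days)
  occ <- function(state) {
    x <- trace[[state]]
    if (settings$half_cycle) (x[cyc] + x[cyc + 1L]) / 2 else x[cyc + 1L]
  }
  pfs <- occ("pfs"); pd <- occ("pd")
  newly_dead <- trace$newly_dead[cyc + 1L]

  drug <- drug_cost_per_cycle(strategy, inputs, cyc)
  cemi <- attr(drug, "cemiplimab")
  chemo <- as.numeric(drug) - cemi
  fu <- inputs$care_costs[["followup_per_cycle"]]
  bsc <- inputs$care_costs[["bsc_per_cycle"]]
  eol <- inputs$care_costs[["end_of_life"]]

  inc <- inputs$teae_incidence[[strategy$arm]]
  teae_cost <- sum(inc * inputs$care_costs[names(inc)])
  teae_qaly <- sum(inc * inputs$disutilities[names(inc)]) * cycle_years

  components <- c(
    cemiplimab = sum(pfs * cemi * disc),
    chemo = sum(pfs * chemo * disc),
    followup = sum(pfs * fu * disc),
    bsc = sum(pd * bsc * disc),
    end_of_life = sum(newly_dead * eol * disc),
    teae = teae_cost * disc[1L])
  qaly <- sum((pfs * inputs$utilities[["pfs"]] +
                 pd * inputs$utilities[["pd"]]) * cycle_years * disc) -
    teae_qaly * disc[1L]
  structure(list(total_cost = sum(components),
                 total_qaly = qaly,
                 total_ly = sum((pfs + pd) * cycle_years * disc),
                 total_ly_undisc = sum((pfs + pd) * cycle_years),
                 components = components,
                 arm = strategy$arm),
            class = "arm_totals")
}

#' @export
print.arm_totals <- function(x, ...) {
  cat(sprintf("%s: cost $%.0f, QALY %.3f, LY %.3f (undisc %.3f)\n",
              x$arm, x$total_cost, x$total_qaly, x$total_ly,
              x$total_ly_undisc))
  invisible(x)
}

#' Incremental cost-effectiveness of the cemiplimab arm
#'
#' @param cct,pct [accrue()] results for the cemiplimab and chemotherapy
#'   arms.
#' @return An object of class `ce_result`: an `arms` data frame of per-arm
#'   totals and an `incremental` list with `delta_cost`, `delta_qaly`,
#'   signed `icer` (USD/QALY; `NA` when `delta_qaly` is 0) and a `status`
#'   of `"dominated"` (more costly, less effective), `"dominant"` (less
#'   costly, more effective), `"undefined"` or `""`.
#' @export
compute_icer <- function(cct, pct) {
  stopifnot(inherits(cct, "arm_totals"), inherits(pct, "arm_totals"))
  dc <- cct$total_cost - pct$total_cost
  dq <- cct$total_qaly - pct$total_qaly
  status <- if (dq == 0) "undefined"
  else if (dq < 0 && dc > 0) "dominated"
  else if (dq > 0 && dc < 0) "dominant"
  else ""
  icer <- if (dq == 0) NA_real_ else dc / dq
  arms <- data.frame(
    arm = c(cct$arm, pct$arm),
    total_cost = c(cct$total_cost, pct$total_cost),
    total_ly_disc = c(cct$total_ly, pct$total_ly),
    total_ly_undisc = c(cct$total_ly_undisc, pct$total_ly_undisc),
    total_qaly = c(cct$total_qaly, pct$total_qaly))
  structure(list(arms = arms,
                 incremental = list(delta_cost = dc, delta_qaly = dq,
                                    icer = icer, status = status)),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  print(x$arms, row.names = FALSE)
  inc <- x$incremental
  cat(sprintf("\nDelta cost $%.0f, Delta QALY %.3f, ICER %s USD/QALY %s\n",
              inc$delta_cost, inc$delta_qaly,
              if (is.na(inc$icer)) "undefined" else sprintf("%.0f", inc$icer),
              if (nzchar(inc$status)) paste0("[", inc$status, "]") else ""))
  invisible(x)
}
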