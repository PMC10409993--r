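# Shared fixtures: everything is generated in code at test time.

# Published chemotherapy-arm survival laws (monthly time scale).
pct_os <- weibull_params(0.030040, 1.213530)
pct_pfs <- weibull_params(0.061800, 1.388300)

# A hand-built one-cycle trace: whole cohort progression-free for one
# 21-day cycle (used for single-term accrual checks).
one_cycle_trace <- function() {
  tr <- data.frame(cycle = 0:1, t_months = c(0, 21 / 30.4375),
                   pfs = c(1, 1), pd = c(0, 0), dead = c(0, 0),
                   newly_dead = c(0, 0))
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

# Economic inputs that zero out everything except selected care costs.
bare_inputs <- function(followup = 0, bsc = 0, eol = 0) {
  economic_inputs(
    unit_costs = c(carboplatin = 0, cisplatin = 0, cemiplimab = 0,
                   pemetrexed = 0, paclitaxel = 0),
    care_costs = c(followup_per_cycle = followup, bsc_per_cycle = bsc,
                   end_of_life = eol, anemia = 0, neutropenia = 0),
    teae_incidence = list(CCT = c(anemia = 0, neutropenia = 0),
                          PCT = c(anemia = 0, neutropenia = 0)))
}

# Fabricate per-arm totals for incremental arithmetic checks.
fake_totals <- function(cost, qaly, arm = "CCT") {
  structure(list(total_cost = cost, total_qaly = qaly, total_ly = qaly,
                 total_ly_undisc = qaly, components = numeric(0), arm = arm),
            class = "arm_totals")
}
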