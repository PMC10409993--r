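test_that("per-cycle drug costs follow the dosing arithmetic", {
  inputs <- economic_inputs()
  cct <- strategy_definition("CCT")
  pct <- strategy_definition("PCT")
  # cemiplimab: 350 mg flat at 1521.38 USD per 100 mg
  cost1 <- drug_cost_per_cycle(cct, inputs, 1)
  expect_equal(unname(attr(cost1, "cemiplimab")), 3.5 * 1521.38)
  # cemiplimab stops after the 108-week cap (36 cycles)
  expect_equal(unname(attr(drug_cost_per_cycle(cct, inputs, 36), "cemiplimab")),
               5324.83)
  expect_equal(unname(attr(drug_cost_per_cycle(cct, inputs, 37), "cemiplimab")),
               0)
  # pemetrexed maintenance: 500 mg/m2 x 1.72 m2 = 860 mg -> 8.6 x 6.51
  pem <- 8.6 * 6.51
  pem_frac_pct <- 0.299 + 0.104
  expect_equal(as.numeric(drug_cost_per_cycle(pct, inputs, 5)),
               pem_frac_pct * pem)
  # the paclitaxel fraction contributes nothing after induction
  inputs_pac <- economic_inputs(regimen_mix = list(
    CCT = c(pem_carbo = 0, pem_cis = 0, pac_carbo = 0.9, pac_cis = 0.1),
    PCT = c(pem_carbo = 0, pem_cis = 0, pac_carbo = 0.9, pac_cis = 0.1)))
  expect_equal(as.numeric(drug_cost_per_cycle(pct, inputs_pac, 5)), 0)
  # induction cycle: regimen-weighted backbone (hand arithmetic)
  carbo <- 5 * (70 + 25) * 3.93 / 100
  cis <- 75 * 1.72 * 11.25 / 100
  pac <- 200 * 1.72 * 33.68 / 100
  by_hand <- 0.299 * (pem + carbo) + 0.104 * (pem + cis) +
    0.532 * (pac + carbo) + 0.065 * (pac + cis)
  expect_equal(as.numeric(drug_cost_per_cycle(pct, inputs, 1)), by_hand)
  expect_error(drug_cost_per_cycle(pct, inputs, 0), "starts at 1")
})

test_that("regimen mixes must cover the known backbones and sum to one", {
  expect_error(economic_inputs(regimen_mix = list(
    CCT = c(pem_carbo = 0.5, pem_cis = 0.1, pac_carbo = 0.3, pac_cis = 0.2),
    PCT = c(pem_carbo = 0.299, pem_cis = 0.104, pac_carbo = 0.532,
            pac_cis = 0.065))), "sum to 1")
  expect_error(economic_inputs(regimen_mix = list(
    CCT = c(gem_carbo = 0.5, pem_cis = 0.1, pac_carbo = 0.3, pac_cis = 0.1),
    PCT = c(pem_carbo = 0.299, pem_cis = 0.104, pac_carbo = 0.532,
            pac_cis = 0.065))), "unknown regimen key")
})

test_that("single-cycle accrual reproduces a hand-computed total", {
  tr <- one_cycle_trace()
  set0 <- model_settings(discount_rate = 0, half_cycle = FALSE)
  tot <- accrue(tr, strategy_definition("PCT"), bare_inputs(followup = 92.69),
                set0)
  expect_equal(tot$total_cost, 92.69)
  expect_equal(tot$total_qaly, 0.804 * 21 / 365.25)
  expect_equal(tot$total_ly, 21 / 365.25)
})

test_that("an empty trace accrues nothing", {
  tr <- one_cycle_trace()[1, ]
  class(tr) <- c("cohort_trace", "data.frame")
  tot <- accrue(tr, strategy_definition("PCT"), economic_inputs())
  expect_equal(tot$total_cost, 0)
  expect_equal(tot$total_qaly, 0)
})

test_that("arm totals are affine in every unit cost", {
  # finite differences at two price points give the same slope
  for (nm in c("cost_cemiplimab", "cost_pemetrexed", "cost_bsc",
               "cost_followup", "cost_end_of_life")) {
    base <- base_params()[[nm]]
    cost_at <- function(v) {
      ov <- list(); ov[[nm]] <- v
      attr(evaluate_ce(overrides = ov), "cct")$total_cost
    }
    d1 <- cost_at(base + 10) - cost_at(base)
    d2 <- cost_at(base + 20) - cost_at(base + 10)
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_gte(d1, 0)
  }
})

test_that("raising the cemiplimab price raises incremental cost and ICER", {
  lo <- evaluate_ce(overrides = list(cost_cemiplimab = 1217.10))
  hi <- evaluate_ce(overrides = list(cost_cemiplimab = 1825.65))
  expect_gt(hi$incremental$delta_cost, lo$incremental$delta_cost)
  expect_gt(hi$incremental$icer, lo$incremental$icer)
})

test_that("zero discount rate makes discounted and undiscounted totals equal", {
  res <- evaluate_ce(overrides = list(discount_rate = 0))
  expect_equal(res$arms$total_ly_disc, res$arms$total_ly_undisc)
})

test_that("incremental arithmetic keeps signs and dominance flags", {
  r <- compute_icer(fake_totals(100, 2), fake_totals(0, 0, "PCT"))
  expect_equal(r$incremental$icer, 50)
  expect_equal(r$incremental$status, "")
  dom <- compute_icer(fake_totals(100, -0.5), fake_totals(0, 0, "PCT"))
  expect_equal(dom$incremental$status, "dominated")
  expect_equal(dom$incremental$icer, -200)  # signed, not absolute-valued
  dnt <- compute_icer(fake_totals(-100, 0.5), fake_totals(0, 0, "PCT"))
  expect_equal(dnt$incremental$status, "dominant")
  und <- compute_icer(fake_totals(100, 1), fake_totals(0, 1, "PCT"))
  expect_true(is.na(und$incremental$icer))
  expect_equal(und$incremental$status, "undefined")
})
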