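test_that("tornado entries bracket the base case and sort by spread", {
  specs <- default_param_specs()
  # a collapsed range produces zero spread
  flat <- specs[specs$name == "cost_bsc", ]
  flat$low <- flat$high <- flat$base
  tor <- one_way_sa(rbind(flat, specs[specs$name == "hr_os", ]))
  expect_equal(tor$spread[tor$param == "cost_bsc"], 0)
  base_icer <- evaluate_ce()$incremental$icer
  expect_equal(attr(tor, "icer_base"), base_icer)
  expect_equal(tor$spread, sort(tor$spread, decreasing = TRUE))
  # setting a parameter to its base reproduces the base ICER
  expect_equal(tor$icer_low[tor$param == "cost_bsc"], base_icer)
  expect_error(one_way_sa(data.frame(name = "hr_os", base = 0.7, low = 0.9,
                                     high = 0.5, dist = "normal")),
               "low > high|low <= base")
})

test_that("the ICER is monotone in the overall-survival hazard ratio", {
  icers <- vapply(c(0.53, 0.71, 0.93), function(h)
    evaluate_ce(overrides = list(hr_os = h))$incremental$icer, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("survival and treatment-cost parameters dominate the tornado", {
  tor <- one_way_sa()
  # the OS hazard ratio leads; both hazard ratios and the cemiplimab price
  # sit among the leading drivers (alongside the OS shape and the
  # progression-free utility, whose ranges are also wide)
  expect_equal(tor$param[1], "hr_os")
  expect_true(all(c("hr_os", "cost_cemiplimab", "hr_pfs") %in% tor$param[1:5]))
})

test_that("sampled distributions match their moments and supports", {
  specs <- default_param_specs()
  set.seed(99)
  draws <- sample_psa_inputs(specs[specs$name == "utility_pfs", ], 10000)
  expect_lt(abs(mean(draws$utility_pfs) - 0.804) / 0.804, 0.01)
  expect_true(all(draws$utility_pfs >= 0 & draws$utility_pfs <= 1))
  g <- sample_psa_inputs(specs[specs$dist == "gamma", ], 500)
  expect_true(all(g > 0))
  f <- sample_psa_inputs(specs[specs$name == "discount_rate", ], 100)
  expect_true(all(f$discount_rate == 0.05))
  h <- sample_psa_inputs(specs[specs$name == "hr_os", ], 5000)
  expect_true(all(h$hr_os > 0))
  expect_lt(abs(mean(h$hr_os) - 0.71), 0.01)
  bad <- data.frame(name = "x", base = 1.5, low = 1, high = 2, dist = "beta")
  expect_error(sample_psa_inputs(bad, 10), "outside \\(0, 1\\)")
})

test_that("identical seeds give identical Monte Carlo samples", {
  a <- run_psa(n_iter = 40, seed = 123)
  b <- run_psa(n_iter = 40, seed = 123)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$samples), 40)
})

test_that("the acceptability curve is a probability from one sample set", {
  psa <- run_psa(n_iter = 60, seed = 11)
  grid <- seq(0, 5e5, by = 5e4)
  cc <- ceac(psa, grid)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_identical(cc, ceac(psa, grid))  # no re-sampling per threshold
  # willingness-to-pay -> infinity: probability of any QALY gain
  expect_equal(ceac(psa, 1e12)$probability,
               mean(psa$samples$delta_qaly > 0))
})

test_that("deterministic price threshold solves ICER(price) = threshold", {
  wtp <- 38201
  th <- threshold_price(wtp, "deterministic")
  expect_equal(th$status, "ok")
  at_star <- evaluate_ce(overrides = list(cost_cemiplimab = th$price))
  expect_equal(at_star$incremental$icer / wtp, 1, tolerance = 1e-6)
  # a threshold below the drug-free incremental cost ratio cannot be met
  none <- threshold_price(100, "deterministic")
  expect_equal(none$status, "never cost-effective at any price")
  expect_true(is.na(none$price))
})

test_that("probabilistic and deterministic thresholds agree within 10%", {
  psa <- run_psa(n_iter = 400, seed = 21)
  det <- threshold_price(38201, "deterministic")
  p50 <- threshold_price(38201, "psa50", psa = psa)
  expect_equal(p50$status, "ok")
  expect_lt(abs(p50$price - det$price) / det$price, 0.10)
  expect_lt(abs(p50$acceptability - 0.5), 0.011)
})

test_that("subgroup evaluation with whole-population ratios is the base case", {
  base <- evaluate_ce()
  sub <- run_subgroup(0.56, 0.71)
  expect_equal(sub$incremental$icer, base$incremental$icer)
  expect_equal(sub$arms, base$arms)
  expect_error(run_subgroup(-1, 0.7), "positive")
})

test_that("a harmful OS hazard ratio produces a signed dominated ICER", {
  fem <- run_subgroup(0.90, 2.11)
  expect_lt(fem$incremental$icer, 0)
  expect_equal(fem$incremental$status, "dominated")
  expect_gt(fem$incremental$delta_cost, 0)
  expect_lt(fem$incremental$delta_qaly, 0)
})

test_that("the subgroup table carries 21 labelled rows with finite ICERs", {
  sub <- subgroup_analysis()
  expect_equal(nrow(sub), 21)
  expect_true(all(is.finite(sub$icer)))
  expect_true(all(sub$hr_pfs > 0 & sub$hr_os > 0))
  expect_true(all(sub$hr_pfs_low <= sub$hr_pfs &
                    sub$hr_pfs <= sub$hr_pfs_high))
})
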