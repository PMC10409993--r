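test_that("curve and risk-table validation names the offending input", {
  expect_error(digitized_curve(c(0, 2, 2), c(1, 0.8, 0.6)),
               "strictly increasing.*index 3")
  expect_error(digitized_curve(c(0, 2), c(1, 1.2)), "\\[0, 1\\].*index 2")
  expect_error(digitized_curve(c(0, 2, 4), c(1, 0.5, 0.8), repair = FALSE),
               "non-increasing.*index 3")
  expect_warning(digitized_curve(c(0, 2, 4), c(1, 0.5, 0.58)),
                 "repair changed")
  # jitter below the 0.005 reporting threshold is repaired silently
  expect_silent(digitized_curve(c(0, 2, 4), c(1, 0.5, 0.504)))
  expect_error(risk_table(c(1, 5), c(100, 50)), "start at time 0")
  expect_error(risk_table(c(0, 5), c(100, 120)), "non-increasing")
})

test_that("a single total drop reconstructs as all events, no censoring", {
  curve <- digitized_curve(c(0, 5), c(1, 0))
  risk <- risk_table(c(0, 6), c(10, 0))
  ipd <- reconstruct_pseudo_ipd(curve, risk)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$event), 10)
  expect_true(all(ipd$time == 5))
})

test_that("a flat curve with constant at-risk yields zero events", {
  curve <- digitized_curve(c(0, 6, 12), c(1, 1, 1))
  risk <- risk_table(c(0, 6, 12), c(50, 50, 50))
  ipd <- reconstruct_pseudo_ipd(curve, risk)
  expect_equal(sum(ipd$event), 0)
  expect_true(all(ipd$time >= 12))
  expect_equal(nrow(ipd), 50)
})

test_that("reconstruction conserves patients per interval and overall", {
  spec <- sim_spec(n_pct = 154, dropout_rate = 0.02,
                   admin_censor_time = 20, digitize_grid = 0.5, seed = 31)
  trial <- simulate_trial(spec)
  d <- digitize(trial$pct$os, spec)
  ipd <- reconstruct_pseudo_ipd(d$curve, d$risk)
  expect_equal(nrow(ipd), d$risk$n_risk[1])
  expect_equal(sum(ipd$event) + sum(ipd$event == 0), d$risk$n_risk[1])
  # removals within each interior right-closed risk interval match the
  # published decline in the at-risk count (the final interval also holds
  # the administratively censored records, which are still at risk there)
  rt <- as.data.frame(d$risk)
  for (i in seq_len(nrow(rt) - 2)) {
    removed <- sum(ipd$time > rt$time[i] & ipd$time <= rt$time[i + 1])
    expect_equal(removed, rt$n_risk[i] - rt$n_risk[i + 1])
  }
})

test_that("reconstructed KM median matches the closed-form Weibull median", {
  # monthly digitization grid, no rounding, no dropout before 24 months
  spec <- sim_spec(true_pfs = pct_pfs, n_pct = 154, dropout_rate = 0,
                   admin_censor_time = 24, digitize_grid = 1,
                   coord_decimals = 10, seed = 7)
  trial <- simulate_trial(spec)
  d <- digitize(trial$pct$pfs, spec)
  ipd <- reconstruct_pseudo_ipd(d$curve, d$risk)
  km <- km_estimate(ipd)
  med <- km$points$time[which(km$points$survival <= 0.5)[1]]
  expect_lt(abs(med - (log(2) / 0.0618)^(1 / 1.3883)), 0.5)
})

test_that("round trip matches the digitized curve within 0.02 (noise-free)", {
  for (seed in c(11, 12)) {
    spec <- sim_spec(n_pct = 154, dropout_rate = 0.02,
                     admin_censor_time = 24, digitize_grid = 1,
                     coord_decimals = 10, seed = seed)
    trial <- simulate_trial(spec)
    for (endpoint in c("os", "pfs")) {
      d <- digitize(trial$pct[[endpoint]], spec)
      ipd <- reconstruct_pseudo_ipd(d$curve, d$risk)
      km <- km_estimate(ipd)
      err <- max(abs(curve_survival_at(km, d$curve$points$time) -
                       d$curve$points$survival))
      expect_lt(err, 0.02)
    }
  }
})

test_that("km_estimate is the product-limit estimator", {
  # all-event case: empirical survival steps
  ipd <- pseudo_ipd(1:5, rep(1, 5))
  km <- km_estimate(ipd)
  expect_equal(km$points$survival, c(1, 0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$points$time[1], 0)
  expect_equal(km$points$survival[1], 1)
  # hand product-limit with censoring: event at 1 (3 at risk), censor at 2,
  # event at 3 (1 at risk): S = 2/3 then 0
  toy <- pseudo_ipd(c(1, 2, 3), c(1, 0, 1))
  km2 <- km_estimate(toy)
  expect_equal(curve_survival_at(km2, 1), 2 / 3)
  expect_equal(curve_survival_at(km2, 3), 0)
  expect_error(km_estimate(pseudo_ipd(numeric(0), integer(0))),
               "at least one record")
})

test_that("curve CSV i/o round-trips", {
  curve <- digitized_curve(c(0, 3, 6), c(1, 0.8, 0.55), arm = "PCT")
  risk <- risk_table(c(0, 6), c(154, 80))
  fc <- tempfile(fileext = ".csv"); fr <- tempfile(fileext = ".csv")
  write_digitized_curve(curve, fc)
  write_risk_table(risk, fr)
  expect_equal(read_digitized_curve(fc, arm = "PCT"), curve)
  expect_equal(as.data.frame(read_risk_table(fr)), as.data.frame(risk))
})
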