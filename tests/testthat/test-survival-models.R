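test_that("exponential fit equals the closed-form censored MLE", {
  # rate = events / total follow-up time, censored or not
  set.seed(5)
  ipd <- pseudo_ipd(c(rexp(80, 0.1), rep(12, 20)),
                    c(rep(1, 80), rep(0, 20)))
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(unname(fit$params["rate"]), sum(ipd$event) / sum(ipd$time),
               tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("information criteria follow their formulas for every family", {
  set.seed(6)
  ipd <- simulate_ipd(pct_pfs, 300, admin_censor_time = 18)
  for (fam in c("exponential", "weibull", "loglogistic", "lognormal")) {
    f <- fit_parametric(ipd, fam)
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$loglik)
    expect_equal(f$n, 300)
  }
})

test_that("weibull MLE recovers simulation truth within 5% at n = 2000", {
  set.seed(42)
  ipd <- simulate_ipd(weibull_params(0.0300, 1.2135), 2000)
  fit <- fit_parametric(ipd, "weibull")
  expect_lt(abs(fit$params[["scale"]] - 0.0300) / 0.0300, 0.05)
  expect_lt(abs(fit$params[["shape"]] - 1.2135) / 1.2135, 0.05)
})

test_that("weibull reduces to the exponential when the shape is 1", {
  set.seed(43)
  ipd <- simulate_ipd(weibull_params(0.05, 1), 1000)
  wb <- fit_parametric(ipd, "weibull")
  ex <- fit_parametric(ipd, "exponential")
  expect_lt(abs(wb$params[["shape"]] - 1), 0.06)
  expect_lt(abs(wb$loglik - ex$loglik), 0.5)
})

test_that("parameter recovery median error stays below 10% over 20 replicates", {
  rel <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    set.seed(100 + r)
    ipd <- simulate_ipd(pct_pfs, 500, admin_censor_time = 24)
    fit <- fit_parametric(ipd, "weibull")
    rel[r, ] <- abs(c(fit$params[["scale"]] - 0.0618,
                      fit$params[["shape"]] - 1.3883)) / c(0.0618, 1.3883)
  }
  expect_lt(median(rel[, 1]), 0.10)
  expect_lt(median(rel[, 2]), 0.10)
})

test_that("selection minimizes AIC with BIC and family-order tie-breaks", {
  mk <- function(family, aic, bic, n = 154)
    structure(list(family = family, aic = aic, bic = bic, n = n,
                   loglik = NA, k = 2, params = c(a = 1, b = 2),
                   converged = TRUE), class = "parametric_fit")
  expect_equal(select_model(list(mk("weibull", 210, 211),
                                 mk("lognormal", 204, 208)))$aic, 204)
  # AIC tie -> lower BIC
  expect_equal(select_model(list(mk("weibull", 204, 212),
                                 mk("lognormal", 204, 208)))$family,
               "lognormal")
  # full tie -> family order
  expect_equal(select_model(list(mk("lognormal", 204, 208),
                                 mk("weibull", 204, 208)))$family, "weibull")
  expect_error(select_model(list(mk("weibull", 204, 208, n = 100),
                                 mk("lognormal", 204, 208, n = 154))),
               "differing n")
  expect_error(select_model(list()), "non-empty")
})

test_that("the Weibull is selected for data simulated from a Weibull", {
  set.seed(77)
  ipd <- simulate_ipd(pct_pfs, 500, admin_censor_time = 24)
  fits <- lapply(c("exponential", "weibull", "loglogistic", "lognormal"),
                 function(f) fit_parametric(ipd, f))
  best <- select_model(fits)
  expect_equal(best$family, "weibull")
  expect_equal(nrow(attr(best, "report")), 4)
})

test_that("hazard-ratio scaling multiplies the scale and keeps the shape", {
  os <- scale_by_hr(pct_os, 0.71)
  expect_equal(round(os$scale, 6), 0.021328)
  expect_equal(os$shape, 1.213530)
  pfs <- scale_by_hr(pct_pfs, 0.56)
  expect_equal(round(pfs$scale, 6), 0.034608)
  expect_equal(pfs$shape, 1.388300)
  expect_equal(scale_by_hr(pct_os, 1), pct_os)
  expect_error(scale_by_hr(pct_os, 0), "positive")
  expect_error(scale_by_hr(pct_os, hazard_ratio(1)), NA)
  expect_error(hazard_ratio(0.5, 0.6, 0.9), "within its CI")
})

test_that("the hazard ratio is exact at every time under a shared shape", {
  tt <- c(0.1, 1, 5, 13.28, 40, 72)
  for (hr in c(0.42, 0.71, 1.28, 2.11)) {
    scaled <- scale_by_hr(pct_os, hr)
    expect_equal(hazard_at(scaled, tt) / hazard_at(pct_os, tt),
                 rep(hr, length(tt)))
  }
})

test_that("survival function matches its closed form and median", {
  expect_equal(survival_at(pct_os, 0), 1)
  med <- (log(2) / 0.030040)^(1 / 1.213530)
  expect_equal(survival_at(pct_os, med), 0.5)
  expect_equal(weibull_median(pct_os), med)
  set.seed(8)
  tt <- runif(10, 0, 80)
  expect_equal(survival_at(pct_pfs, tt), exp(-0.0618 * tt^1.3883))
  expect_error(survival_at(pct_os, -1), "non-negative")
  expect_error(weibull_params(-1, 2), "positive")
})
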