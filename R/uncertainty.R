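#' Sensitivity-analysis parameter specifications
#'
#' One row per model parameter: base value, low/high range (the trial's
#' 95% confidence interval where reported, otherwise +/- 20% of base) and
#' the distribution assigned for probabilistic analysis (`gamma` for
#' costs and clearance, `beta` for probabilities/utilities, `normal`
#' truncated at zero for hazard ratios and body surface area, `fixed` for
#' the discount rate). The chemotherapy-arm Weibull scale and shape
#' parameters are included at +/- 20% for the one-way analysis but are
#' held `fixed` in probabilistic analysis.
#'
#' @param include_weibull Include the four Weibull survival parameters
#'   (default `TRUE`).
#' @return A data frame with columns `name`, `base`, `low`, `high`,
#'   `dist`.
#' @export
default_param_specs <- function(include_weibull = TRUE) {
  spec <- function(name, base, low, high, dist)
    data.frame(name = name, base = base, low = low, high = high, dist = dist)
  pm20 <- function(name, base, dist = "fixed")
    spec(name, base, 0.8 * base, 1.2 * base, dist)
  out <- rbind(
    spec("cost_carboplatin", 3.93, 3.15, 4.72, "gamma"),
    spec("cost_cisplatin", 11.25, 9.00, 13.50, "gamma"),
    spec("cost_cemiplimab", 1521.38, 1217.10, 1825.65, "gamma"),
    spec("cost_pemetrexed", 6.51, 5.21, 7.81, "gamma"),
    spec("cost_paclitaxel", 33.68, 26.94, 40.42, "gamma"),
    spec("cost_neutropenia", 82.32, 65.86, 98.78, "gamma"),
    spec("cost_anemia", 496.80, 397.44, 596.16, "gamma"),
    spec("cost_followup", 92.69, 74.15, 111.22, "gamma"),
    spec("cost_end_of_life", 2665.11, 2132.09, 3198.13, "gamma"),
    spec("cost_bsc", 365.51, 292.41, 438.62, "gamma"),
    spec("inc_anemia_cct", 0.099, 0.079, 0.119, "beta"),
    spec("inc_neutropenia_cct", 0.058, 0.046, 0.069, "beta"),
    spec("inc_anemia_pct", 0.065, 0.052, 0.078, "beta"),
    spec("inc_neutropenia_pct", 0.059, 0.047, 0.071, "beta"),
    spec("hr_os", 0.710, 0.530, 0.93, "normal"),
    spec("hr_pfs", 0.560, 0.440, 0.70, "normal"),
    spec("utility_pfs", 0.804, 0.643, 0.965, "beta"),
    spec("utility_pd", 0.321, 0.257, 0.385, "beta"),
    spec("disutility_neutropenia", 0.20, 0.16, 0.24, "beta"),
    spec("disutility_anemia", 0.073, 0.058, 0.088, "beta"),
    spec("bsa", 1.72, 1.38, 2.06, "normal"),
    spec("crcl", 70, 52.5, 87.5, "gamma"),
    spec("discount_rate", 0.05, 0, 0.08, "fixed"),
    spec("mix_cct_pem_carbo", 0.369, 0.295, 0.442, "beta"),
    spec("mix_cct_pem_cis", 0.083, 0.067, 0.100, "beta"),
    spec("mix_cct_pac_carbo", 0.494, 0.395, 0.592, "beta"),
    spec("mix_cct_pac_cis", 0.054, 0.044, 0.065, "beta"),
    spec("mix_pct_pem_carbo", 0.299, 0.239, 0.358, "beta"),
    spec("mix_pct_pem_cis", 0.104, 0.083, 0.125, "beta"),
    spec("mix_pct_pac_carbo", 0.532, 0.426, 0.639, "beta"),
    spec("mix_pct_pac_cis", 0.065, 0.052, 0.078, "beta"))
  if (include_weibull)
    out <- rbind(out,
                 pm20("wb_os_pct_scale", 0.030040),
                 pm20("wb_os_pct_shape", 1.213530),
                 pm20("wb_pfs_pct_scale", 0.061800),
                 pm20("wb_pfs_pct_shape", 1.388300))
  if (any(out$low > out$base | out$base > out$high))
    stop("each spec must satisfy low <= base <= high")
  out
}

#' One-way (deterministic) sensitivity analysis
#'
#' Each parameter is set in turn to its low and high value with all others
#' at base, and the incremental cost-effectiveness ratio recomputed.
#'
#' @param specs Parameter specification data frame
#'   ([default_param_specs()]).
#' @param params Base parameter list ([base_params()]).
#' @param settings A [model_settings()].
#' @return A data frame `param, base, low, high, icer_low, icer_high,
#'   spread`, sorted by decreasing spread (tornado order), with the
#'   base-case ICER as attribute `"icer_base"`.
#' @export
one_way_sa <- function(specs = default_param_specs(),
                       params = base_params(),
                       settings = model_settings()) {
  if (any(specs$low > specs$high)) stop("spec with low > high")
  icer_base <- evaluate_ce(params, settings)$incremental$icer
  icer_at <- function(name, value) {
    ov <- list(); ov[[name]] <- value
    evaluate_ce(params, settings, overrides = ov)$incremental$icer
  }
  lo <- mapply(icer_at, specs$name, specs$low)
  hi <- mapply(icer_at, specs$name, specs$high)
  out <- data.frame(param = specs$name, base = specs$base,
                    low = specs$low, high = specs$high,
                    icer_low = lo, icer_high = hi,
                    spread = abs(hi - lo))
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "icer_base") <- icer_base
  out
}

#' Sample parameter sets for probabilistic analysis
#'
#' Distributions are moment-matched to the base value and an SD derived
#' from the printed range treated as a 95% interval:
#' `sd = (high - low) / 3.92`. Gamma: `shape = (base/sd)^2`,
#' `rate = base/sd^2`. Beta: matched to mean `base` and that SD. Normal:
#' mean `base`, that SD, truncated at zero. `fixed` parameters keep their
#' base value in every draw. Draws are independent across parameters; the
#' caller seeds the RNG.
#'
#' @param specs Specification data frame ([default_param_specs()]).
#' @param n Number of parameter sets.
#' @return A data frame with `n` rows, one column per parameter.
#' @export
sample_psa_inputs <- function(specs, n) {
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    sd <- (s$high - s$low) / 3.92
    switch(s$dist,
      fixed = rep(s$base, n),
      gamma = {
        if (s$base <= 0 || sd <= 0) stop("gamma requires positive base/sd: ", s$name)
        stats::rgamma(n, shape = (s$base / sd)^2, rate = s$base / sd^2)
      },
      beta = {
        m <- s$base
        if (m <= 0 || m >= 1)
          stop("beta mean outside (0, 1) for ", s$name)
        v <- m * (1 - m) / sd^2 - 1
        if (v <= 0) stop("infeasible beta moment match for ", s$name)
        stats::rbeta(n, m * v, (1 - m) * v)
      },
      normal = {
        x <- stats::rnorm(n, s$base, sd)
        while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), s$base, sd)
        x
      },
      stop("unknown distribution: ", s$dist))
  })
  names(cols) <- specs$name
  as.data.frame(cols)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions: each iteration samples a
#' full parameter set, rebuilds both strategies and records the
#' incremental cost and QALYs. Survival-curve crossings induced by extreme
#' hazard-ratio draws are handled by clamping progressed-state occupancy
#' at zero (see [model_settings()]).
#'
#' @param n_iter Number of iterations (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param specs Specification data frame; Weibull parameters are fixed.
#' @param params Base parameter list.
#' @param settings A [model_settings()].
#' @return An object of class `psa_result`: a `samples` data frame
#'   (`iter`, `delta_cost`, `delta_qaly`, `cemi_cost` — the discounted
#'   cemiplimab spend of that iteration), `n_iter` and `seed`.
#' @export
run_psa <- function(n_iter = 1000, seed = NULL,
                    specs = default_param_specs(),
                    params = base_params(),
                    settings = model_settings()) {
  if (n_iter < 1) stop("'n_iter' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  settings$crossing <- "clamp"
  draws <- sample_psa_inputs(specs, n_iter)
  rows <- lapply(seq_len(n_iter), function(i) {
    ov <- as.list(draws[i, , drop = FALSE])
    res <- evaluate_ce(params, settings, overrides = ov)
    c(delta_cost = res$incremental$delta_cost,
      delta_qaly = res$incremental$delta_qaly,
      cemi_cost = unname(attr(res, "cct")$components[["cemiplimab"]]))
  })
  samples <- cbind(iter = seq_len(n_iter),
                   as.data.frame(do.call(rbind, rows)))
  structure(list(samples = samples, n_iter = n_iter, seed = seed,
                 draws = draws),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of positive net monetary benefit, `wtp * dQALY - dCost > 0`,
#' across a willingness-to-pay grid, from a single PSA sample set.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay values (USD/QALY).
#' @return Data frame `wtp, probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 400000, by = 10000)) {
  stopifnot(inherits(psa, "psa_result"))
  s <- psa$samples
  prob <- vapply(wtp_grid,
                 function(w) mean(w * s$delta_qaly - s$delta_cost > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Cemiplimab price threshold analysis
#'
#' Finds the cemiplimab price per 100 mg at which the intervention becomes
#' cost-effective at the willingness-to-pay threshold. `deterministic`
#' mode solves `ICER(price) = wtp` in closed form (the incremental cost is
#' affine in the unit price). `psa50` mode scales every PSA iteration's
#' sampled cemiplimab spend by a common price factor and bisects that
#' factor until the acceptability (fraction of iterations with positive
#' net monetary benefit) is within a percentage point of 50%.
#'
#' @param wtp Willingness-to-pay threshold, USD/QALY (default 38201,
#'   three times 2022 Chinese per-capita GDP).
#' @param mode `"deterministic"` or `"psa50"`.
#' @param params,settings Model configuration.
#' @param psa A [run_psa()] result for `psa50` mode; when `NULL` one is
#'   run with `n_iter` and `seed`.
#' @param n_iter,seed PSA size/seed when `psa` is not supplied.
#' @param tol Acceptability tolerance around 0.5 for `psa50` (default
#'   0.01).
#' @return A list: `price` (USD per 100 mg), `fraction_of_base`, `mode`,
#'   `status` (`"ok"` or `"never cost-effective at any price"`), and for
#'   `psa50` the achieved `acceptability`.
#' @export
threshold_price <- function(wtp = 38201,
                            mode = c("deterministic", "psa50"),
                            params = base_params(),
                            settings = model_settings(),
                            psa = NULL, n_iter = 1000, seed = NULL,
                            tol = 0.01) {
  mode <- match.arg(mode)
  base_price <- params$cost_cemiplimab
  if (mode == "deterministic") {
    at_base <- evaluate_ce(params, settings)
    at_zero <- evaluate_ce(params, settings,
                           overrides = list(cost_cemiplimab = 0))
    dq <- at_base$incremental$delta_qaly
    dc1 <- at_base$incremental$delta_cost
    dc0 <- at_zero$incremental$delta_cost
    if (dc1 / dq <= wtp)
      stop("ICER at the current price is already below the threshold")
    if (wtp * dq <= dc0)
      return(list(price = NA_real_, fraction_of_base = NA_real_,
                  mode = mode, status = "never cost-effective at any price"))
    f <- (wtp * dq - dc0) / (dc1 - dc0)
    list(price = f * base_price, fraction_of_base = f, mode = mode,
         status = "ok")
  } else {
    if (is.null(psa)) psa <- run_psa(n_iter = n_iter, seed = seed,
                                     params = params, settings = settings)
    s <- psa$samples
    acc <- function(f)
      mean(wtp * s$delta_qaly - (s$delta_cost - (1 - f) * s$cemi_cost) > 0)
    if (acc(1e-9) < 0.5)
      return(list(price = NA_real_, fraction_of_base = NA_real_,
                  mode = mode, status = "never cost-effective at any price"))
    lo <- 1e-9; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      a <- acc(mid)
      if (abs(a - 0.5) < tol) break
      if (a > 0.5) lo <- mid else hi <- mid
    }
    list(price = mid * base_price, fraction_of_base = mid, mode = mode,
         status = "ok", acceptability = acc(mid))
  }
}

#' Trial subgroup hazard ratios
#'
#' Point estimates and 95% confidence intervals of the progression-free
#' and overall-survival hazard ratios reported for each trial subgroup.
#'
#' @return Data frame `category, subgroup, hr_pfs, hr_pfs_low,
#'   hr_pfs_high, hr_os, hr_os_low, hr_os_high` (21 rows).
#' @export
subgroup_hazard_ratios <- function() {
  sg <- function(category, subgroup, pfs, os)
    data.frame(category = category, subgroup = subgroup,
               hr_pfs = pfs[1], hr_pfs_low = pfs[2], hr_pfs_high = pfs[3],
               hr_os = os[1], hr_os_low = os[2], hr_os_high = os[3])
  rbind(
    sg("Age group (years)", "<65", c(0.53, 0.39, 0.71), c(0.57, 0.40, 0.81)),
    sg("Age group (years)", ">=65", c(0.56, 0.39, 0.81), c(0.88, 0.56, 1.37)),
    sg("Sex", "Male", c(0.48, 0.37, 0.61), c(0.55, 0.41, 0.74)),
    sg("Sex", "Female", c(0.90, 0.50, 1.62), c(2.11, 0.89, 5.03)),
    sg("Race", "White", c(0.54, 0.43, 0.69), c(0.67, 0.50, 0.89)),
    sg("Race", "Non-white", c(0.58, 0.28, 1.20), c(0.79, 0.31, 2.02)),
    sg("Histology", "Squamous", c(0.56, 0.40, 0.79), c(0.56, 0.37, 0.84)),
    sg("Histology", "Non-squamous", c(0.53, 0.39, 0.73), c(0.79, 0.54, 1.14)),
    sg("PD-L1 expression level", "<1%", c(0.76, 0.51, 1.15), c(1.01, 0.63, 1.60)),
    sg("PD-L1 expression level", "1%-49%", c(0.47, 0.33, 0.68), c(0.52, 0.32, 0.83)),
    sg("PD-L1 expression level", ">=50%", c(0.47, 0.31, 0.72), c(0.61, 0.37, 1.02)),
    sg("ECOG PS", "0", c(0.20, 0.09, 0.43), c(0.55, 0.20, 1.49)),
    sg("ECOG PS", "1", c(0.60, 0.47, 0.76), c(0.69, 0.52, 0.92)),
    sg("Region", "Europe", c(0.55, 0.43, 0.70), c(0.67, 0.50, 0.90)),
    sg("Region", "Asia", c(0.52, 0.25, 1.10), c(0.72, 0.27, 1.88)),
    sg("Brain metastasis", "Yes", c(0.53, 0.22, 1.31), c(0.42, 0.14, 1.26)),
    sg("Brain metastasis", "No", c(0.54, 0.43, 0.69), c(0.68, 0.51, 0.90)),
    sg("Cancer stage at screening", "Locally advanced",
       c(0.34, 0.19, 0.62), c(0.54, 0.25, 1.15)),
    sg("Cancer stage at screening", "Metastatic",
       c(0.59, 0.46, 0.75), c(0.69, 0.51, 0.93)),
    sg("Smoking history", "Smokers", c(0.53, 0.42, 0.68), c(0.61, 0.46, 0.82)),
    sg("Smoking history", "Never smokers",
       c(0.65, 0.34, 1.22), c(1.28, 0.53, 3.08)))
}

#' Subgroup cost-effectiveness
#'
#' `run_subgroup()` substitutes subgroup-specific hazard ratios into the
#' model, holding every other parameter at its whole-population value; the
#' chemotherapy-arm survival laws are unchanged. Early survival-curve
#' crossings (possible when a subgroup's OS hazard ratio exceeds 1) are
#' clamped. `subgroup_analysis()` does this for every trial subgroup.
#'
#' @param hr_pfs,hr_os Subgroup hazard ratios (positive).
#' @param params,settings Model configuration.
#' @return `run_subgroup()`: a [compute_icer()] result.
#'   `subgroup_analysis()`: the [subgroup_hazard_ratios()] table with
#'   `delta_cost`, `delta_qaly`, `icer`, `status` columns appended.
#' @export
run_subgroup <- function(hr_pfs, hr_os, params = base_params(),
                         settings = model_settings()) {
  if (hr_pfs <= 0 || hr_os <= 0) stop("hazard ratios must be positive")
  settings$crossing <- "clamp"
  evaluate_ce(params, settings,
              overrides = list(hr_pfs = hr_pfs, hr_os = hr_os))
}

#' @rdname run_subgroup
#' @param table Subgroup table ([subgroup_hazard_ratios()]).
#' @export
subgroup_analysis <- function(table = subgroup_hazard_ratios(),
                              params = base_params(),
                              settings = model_settings()) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    r <- run_subgroup(table$hr_pfs[i], table$hr_os[i], params, settings)
    data.frame(delta_cost = r$incremental$delta_cost,
               delta_qaly = r$incremental$delta_qaly,
               icer = r$incremental$icer,
               status = r$incremental$status)
  })
  cbind(table, do.call(rbind, res))
}
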