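#' Run a configured analysis scenario
#'
#' Configuration-driven entry point tying the stages together. The
#' configuration (a YAML or JSON file, or an equivalent nested list) may
#' contain:
#'
#' * `survival`: where the chemotherapy-arm survival laws come from.
#'   `source: parametric` (default) uses the fitted Weibull parameters of
#'   the base case; `source: files` reads digitized curve / risk-table
#'   CSVs (`os_curve`, `os_risk`, `pfs_curve`, `pfs_risk`), reconstructs
#'   pseudo individual-patient data, fits the four candidate
#'   distributions and selects by AIC/BIC; `source: simulate` does the
#'   same on data generated by [simulate_trial()] (fields of
#'   [sim_spec()] may be overridden in a `sim` block).
#' * `params`: named overrides of [base_params()].
#' * `settings`: named overrides of [model_settings()] arguments.
#' * `analyses`: toggles `base`, `owsa`, `psa`, `threshold`, `subgroups`
#'   (base defaults to on, the rest to off).
#' * `psa`: `n_iter` (default 1000); `threshold`: `wtp` (default 38201).
#'
#' Results are written under `outdir` as CSV files plus a machine-readable
#' `summary.json` and a `run_log.txt` echoing every resolved parameter.
#' Identical configuration and seed yield byte-identical summaries.
#'
#' @param config Path to a YAML/JSON configuration file, or a list.
#' @param outdir Output directory (created if needed).
#' @param seed Seed for all stochastic stages.
#' @return Invisibly, the summary list.
#' @export
run_scenario <- function(config = list(), outdir = tempfile("scenario"),
                         seed = 1L) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a file path")
  known <- c("survival", "params", "settings", "analyses", "psa",
             "threshold", "sim")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  params <- base_params()
  if (length(config$params)) {
    bad <- setdiff(names(config$params), names(params))
    if (length(bad)) stop("unknown params: ", paste(bad, collapse = ", "))
    params[names(config$params)] <- config$params
  }
  # Refitted OS and PFS laws are estimated independently, so hairline
  # curve crossings are expected; the pipeline clamps unless told otherwise.
  settings <- do.call(model_settings,
                      utils::modifyList(list(crossing = "clamp"),
                                        config$settings %||% list()))
  analyses <- utils::modifyList(
    list(base = TRUE, owsa = FALSE, psa = FALSE, threshold = FALSE,
         subgroups = FALSE), config$analyses %||% list())
  src <- (config$survival %||% list(source = "parametric"))$source %||%
    "parametric"

  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("nsclcCEA %s scenario run, seed %d",
       as.character(utils::packageVersion("nsclcCEA")), seed)
  logf("survival source: %s; structure: %s; half_cycle: %s; crossing: %s",
       src, settings$structure, settings$half_cycle, settings$crossing)

  summary <- list(package_version =
                    as.character(utils::packageVersion("nsclcCEA")),
                  seed = seed, survival_source = src)

  if (src %in% c("files", "simulate")) {
    fitted <- if (src == "files") {
      sv <- config$survival
      lapply(list(os = c(sv$os_curve, sv$os_risk),
                  pfs = c(sv$pfs_curve, sv$pfs_risk)), function(p) {
        reconstruct_pseudo_ipd(read_digitized_curve(p[1]),
                               read_risk_table(p[2]))
      })
    } else {
      spec <- do.call(sim_spec, utils::modifyList(list(seed = seed),
                                                  config$sim %||% list()))
      trial <- simulate_trial(spec)
      dig <- lapply(trial$pct, digitize, spec = spec)
      lapply(dig, function(d) reconstruct_pseudo_ipd(d$curve, d$risk))
    }
    for (endpoint in names(fitted)) {
      fits <- lapply(c("exponential", "weibull", "loglogistic", "lognormal"),
                     function(f) fit_parametric(fitted[[endpoint]], f))
      best <- select_model(fits)
      utils::write.csv(attr(best, "report"),
                       file.path(outdir, paste0("fit_", endpoint, ".csv")),
                       row.names = FALSE)
      logf("%s: selected %s (AIC %.2f)", endpoint, best$family, best$aic)
      if (best$family == "weibull") {
        wp <- as_weibull_params(best)
        params[[paste0("wb_", endpoint, "_pct_scale")]] <- wp$scale
        params[[paste0("wb_", endpoint, "_pct_shape")]] <- wp$shape
      } else {
        logf("%s: selected family is not Weibull; keeping base parameters",
             endpoint)
      }
    }
  }
  for (nm in names(params)) logf("param %s = %s", nm,
                                 format(params[[nm]], digits = 10))

  if (analyses$base) {
    res <- evaluate_ce(params, settings)
    arms <- res$arms
    inc <- data.frame(arm = "incremental",
                      total_cost = res$incremental$delta_cost,
                      total_ly_disc = NA, total_ly_undisc = NA,
                      total_qaly = res$incremental$delta_qaly)
    utils::write.csv(rbind(arms, inc), file.path(outdir, "base_case.csv"),
                     row.names = FALSE)
    summary$base <- list(arms = arms, incremental = res$incremental)
  }
  if (analyses$owsa) {
    tor <- one_way_sa(default_param_specs(), params, settings)
    utils::write.csv(tor[, c("param", "icer_low", "icer_high", "spread")],
                     file.path(outdir, "tornado.csv"), row.names = FALSE)
    summary$owsa <- list(icer_base = attr(tor, "icer_base"),
                         top_drivers = tor$param[1:3])
  }
  psa <- NULL
  if (analyses$psa || analyses$threshold) {
    n_iter <- (config$psa %||% list())$n_iter %||% 1000
    psa <- run_psa(n_iter = n_iter, seed = seed, params = params,
                   settings = settings)
  }
  wtp <- (config$threshold %||% list())$wtp %||% 38201
  if (analyses$psa) {
    utils::write.csv(psa$samples[, c("iter", "delta_cost", "delta_qaly")],
                     file.path(outdir, "psa_samples.csv"), row.names = FALSE)
    cc <- ceac(psa)
    utils::write.csv(cc, file.path(outdir, "ceac.csv"), row.names = FALSE)
    summary$psa <- list(n_iter = psa$n_iter,
                        acceptability_at_wtp =
                          mean(wtp * psa$samples$delta_qaly -
                                 psa$samples$delta_cost > 0))
  }
  if (analyses$threshold) {
    th_det <- threshold_price(wtp, "deterministic", params, settings)
    th_psa <- threshold_price(wtp, "psa50", params, settings, psa = psa)
    utils::write.csv(
      data.frame(mode = c("deterministic", "psa50"),
                 price = c(th_det$price, th_psa$price),
                 fraction_of_base = c(th_det$fraction_of_base,
                                      th_psa$fraction_of_base)),
      file.path(outdir, "threshold.csv"), row.names = FALSE)
    summary$threshold <- list(wtp = wtp, deterministic = th_det$price,
                              psa50 = th_psa$price)
  }
  if (analyses$subgroups) {
    sub <- subgroup_analysis(params = params, settings = settings)
    utils::write.csv(sub, file.path(outdir, "subgroups.csv"),
                     row.names = FALSE)
    summary$subgroups <- sub[, c("category", "subgroup", "icer", "status")]
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
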