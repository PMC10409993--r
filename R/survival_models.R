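#' Weibull survival parameters (hazard-scale form)
#'
#' The survival law used throughout the model is
#' \deqn{S(t) = \exp(-\lambda t^{\gamma})}
#' with `t` in months, scale \eqn{\lambda > 0} (per month^gamma) and
#' dimensionless shape \eqn{\gamma > 0}. Under this form a hazard ratio
#' acts multiplicatively on \eqn{\lambda} when the shape is shared.
#'
#' @param scale Scale \eqn{\lambda}, positive.
#' @param shape Shape \eqn{\gamma}, positive.
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(0.030040, 1.213530)  # chemotherapy-arm overall survival
#' @export
weibull_params <- function(scale, shape) {
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  if (!is.finite(shape) || shape <= 0) stop("'shape' must be positive")
  structure(list(scale = scale, shape = shape, time_unit = "months"),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull S(t)=exp(-%.6f * t^%.6f), t in months (median %.2f)\n",
              x$scale, x$shape, weibull_median(x)))
  invisible(x)
}

#' Survival, hazard and median of the hazard-scale Weibull
#'
#' @param params A [weibull_params()].
#' @param t Time(s) in months, non-negative.
#' @return `survival_at()`: \eqn{\exp(-\lambda t^\gamma)};
#'   `hazard_at()`: \eqn{\lambda\gamma t^{\gamma-1}};
#'   `weibull_median()`: \eqn{(\ln 2/\lambda)^{1/\gamma}}.
#' @export
survival_at <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  exp(-params$scale * t^params$shape)
}

#' @rdname survival_at
#' @export
hazard_at <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t <= 0)) stop("'t' must be positive for the hazard")
  params$scale * params$shape * t^(params$shape - 1)
}

#' @rdname survival_at
#' @export
weibull_median <- function(params) {
  (log(2) / params$scale)^(1 / params$shape)
}

#' Hazard ratio with confidence interval
#'
#' @param value Point estimate, positive.
#' @param ci_low,ci_high Optional 95% confidence bounds.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(value, ci_low = NA_real_, ci_high = NA_real_) {
  if (!is.finite(value) || value <= 0) stop("hazard ratio must be positive")
  if (is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= value && value <= ci_high))
    stop("hazard ratio point estimate must lie within its CI")
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

#' Derive an intervention-arm Weibull by proportional-hazards scaling
#'
#' With a shared shape, multiplying the hazard by `hr` is exactly
#' multiplying the scale: \eqn{\gamma_{new} = \gamma}, \eqn{\lambda_{new} =
#' HR \times \lambda}. This is how the cemiplimab-arm curves are obtained
#' from the chemotherapy-arm fits and the trial hazard ratios.
#'
#' @param base A [weibull_params()] for the reference arm.
#' @param hr A [hazard_ratio()] or a positive number.
#' @return A [weibull_params()].
#' @examples
#' scale_by_hr(weibull_params(0.030040, 1.213530), 0.71)
#' @export
scale_by_hr <- function(base, hr) {
  stopifnot(inherits(base, "weibull_params"))
  h <- if (inherits(hr, "hazard_ratio")) hr$value else hr
  if (!is.finite(h) || h <= 0) stop("hazard ratio must be positive")
  weibull_params(h * base$scale, base$shape)
}

.families <- c("exponential", "weibull", "loglogistic", "lognormal")
.flexsurv_dist <- c(exponential = "exp", weibull = "weibullPH",
                    loglogistic = "llogis", lognormal = "lnorm")

#' Fit a parametric survival distribution to pseudo-IPD
#'
#' Maximum-likelihood fit under right censoring via
#' [flexsurv::flexsurvreg()]. The Weibull is fitted in proportional-hazards
#' form (`weibullPH`), i.e. directly in the \eqn{S(t)=\exp(-\lambda
#' t^\gamma)} parameterization used by the cohort model. AIC and BIC are
#' recomputed from the achieved log-likelihood: `aic = 2k - 2*loglik`,
#' `bic = k*log(n) - 2*loglik` with `n` the number of records.
#'
#' @param ipd A [pseudo_ipd()] with at least two events.
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`.
#' @return An object of class `parametric_fit`: family, named `params`
#'   vector, `loglik`, `aic`, `bic`, `n`, `k`, `converged`.
#' @export
fit_parametric <- function(ipd, family = .families) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  family <- match.arg(family)
  if (sum(ipd$event) < 2L) stop("at least two events are required")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = .flexsurv_dist[[family]]),
    error = function(e) stop("fit failed for family '", family, "': ",
                             conditionMessage(e)))
  conv <- is.null(fit$opt$convergence) || fit$opt$convergence == 0
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  params <- switch(family,
    exponential = c(rate = unname(est["rate"])),
    weibull     = c(scale = unname(est["scale"]), shape = unname(est["shape"])),
    loglogistic = c(shape = unname(est["shape"]), scale = unname(est["scale"])),
    lognormal   = c(meanlog = unname(est["meanlog"]), sdlog = unname(est["sdlog"])))
  k <- length(params)
  n <- nrow(ipd)
  ll <- fit$loglik
  structure(list(family = family, params = params, loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n = n, k = k, converged = conv),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("%s fit (n=%d): loglik=%.2f AIC=%.2f BIC=%.2f%s\n", x$family,
              x$n, x$loglik, x$aic, x$bic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

#' Select the best-fitting distribution by information criteria
#'
#' Minimizes AIC; ties broken by lower BIC, then by family order
#' exponential < weibull < loglogistic < lognormal.
#'
#' @param fits A non-empty list of [fit_parametric()] results over the same
#'   data (identical `n`).
#' @return The selected `parametric_fit`, with the full comparison table
#'   attached as attribute `"report"` (see [fit_report()]).
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("'fits' must be non-empty")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("all fits must be over the same data (differing n)")
  ord <- order(vapply(fits, `[[`, numeric(1), "aic"),
               vapply(fits, `[[`, numeric(1), "bic"),
               match(vapply(fits, `[[`, character(1), "family"), .families))
  best <- fits[[ord[1L]]]
  attr(best, "report") <- fit_report(fits)
  best
}

#' Comparison table for a set of parametric fits
#'
#' @param fits List of `parametric_fit` objects.
#' @return Data frame `family,loglik,aic,bic,param1,param2,converged`.
#' @export
fit_report <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    p <- unname(f$params)
    data.frame(family = f$family, loglik = f$loglik, aic = f$aic,
               bic = f$bic, param1 = p[1L],
               param2 = if (f$k > 1L) p[2L] else NA_real_,
               converged = f$converged)
  }))
}

#' Convert a Weibull fit to model parameters
#'
#' @param fit A `parametric_fit` with `family == "weibull"`.
#' @return A [weibull_params()].
#' @export
as_weibull_params <- function(fit) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (fit$family != "weibull")
    stop("only Weibull fits can be converted to model parameters")
  weibull_params(fit$params[["scale"]], fit$params[["shape"]])
}
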