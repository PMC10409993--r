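#' Digitized Kaplan-Meier curve
#'
#' Container for coordinates read off a published Kaplan-Meier plot
#' (e.g. with a graph digitizer): ordered (time, survival) pairs in months.
#'
#' @param time Numeric vector of times in months, strictly increasing.
#' @param survival Numeric vector of survival probabilities in `[0, 1]`,
#'   non-increasing.
#' @param arm Optional arm label, e.g. `"PCT"`.
#' @param repair If `TRUE` (default), repair small digitization jitter by
#'   taking a running minimum of the survival values before validation; a
#'   warning is issued when the repair changes any value by more than 0.005.
#' @return An object of class `digitized_curve`: a list with a `points`
#'   data frame (`time`, `survival`) and the `arm` label.
#' @examples
#' digitized_curve(time = c(0, 6, 12), survival = c(1, 0.7, 0.45))
#' @export
digitized_curve <- function(time, survival, arm = "", repair = TRUE) {
  if (length(time) != length(survival) || length(time) < 1L)
    stop("'time' and 'survival' must be non-empty vectors of equal length")
  if (any(diff(time) <= 0)) {
    i <- which(diff(time) <= 0)[1L] + 1L
    stop("digitized times must be strictly increasing (offending index ", i, ")")
  }
  if (time[1L] < 0) stop("digitized times must be non-negative")
  if (any(survival < 0 | survival > 1)) {
    i <- which(survival < 0 | survival > 1)[1L]
    stop("survival values must lie in [0, 1] (offending index ", i, ")")
  }
  if (repair) {
    fixed <- cummin(survival)
    if (max(abs(fixed - survival)) > 0.005)
      warning("monotonicity repair changed a survival value by more than 0.005")
    survival <- fixed
  } else if (any(diff(survival) > 0)) {
    i <- which(diff(survival) > 0)[1L] + 1L
    stop("survival must be non-increasing (offending index ", i, ")")
  }
  structure(list(points = data.frame(time = time, survival = survival),
                 arm = arm),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("Digitized KM curve", if (nzchar(x$arm)) paste0("[", x$arm, "]"), "-",
      nrow(x$points), "points, t in [",
      min(x$points$time), ",", max(x$points$time), "] months\n")
  invisible(x)
}

#' Numbers-at-risk table
#'
#' @param time Numeric vector of times in months, increasing, starting at 0.
#' @param n_risk Integer vector of patients still at risk at each time,
#'   non-increasing; the first entry is the arm's enrolled count.
#' @return An object of class `risk_table` (a data frame).
#' @export
risk_table <- function(time, n_risk) {
  if (length(time) != length(n_risk) || length(time) < 1L)
    stop("'time' and 'n_risk' must be non-empty vectors of equal length")
  if (time[1L] != 0) stop("risk table must start at time 0")
  if (any(diff(time) <= 0)) stop("risk table times must be increasing")
  if (any(n_risk < 0) || any(n_risk != round(n_risk)))
    stop("'n_risk' must be non-negative integers")
  if (any(diff(n_risk) > 0)) stop("'n_risk' must be non-increasing")
  structure(data.frame(time = time, n_risk = as.integer(n_risk)),
            class = c("risk_table", "data.frame"))
}

#' Pseudo individual-patient data
#'
#' @param time Event or censoring times in months.
#' @param event 1 for an event (death/progression), 0 for censoring.
#' @param arm Optional arm label.
#' @return An object of class `pseudo_ipd` (a data frame with columns
#'   `time` and `event`).
#' @export
pseudo_ipd <- function(time, event, arm = "") {
  if (length(time) != length(event)) stop("'time' and 'event' lengths differ")
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("'event' must be 0 or 1")
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pseudo_ipd", "data.frame"), arm = arm)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Inverts the Kaplan-Meier product-limit construction: given the digitized
#' survival coordinates and the published numbers-at-risk, the number of
#' events at each digitized time and the number of censorings in each
#' risk-table interval are solved iteratively so that the implied step
#' function tracks the digitized curve while the implied at-risk counts hit
#' the published numbers at the interval boundaries. Censoring times are
#' assumed uniformly spread within each interval. The procedure is fully
#' deterministic.
#'
#' Patients still at risk after the last digitized time are censored there.
#'
#' @param curve A [digitized_curve()].
#' @param risk A [risk_table()]; must start at time 0 with the arm's
#'   enrolled count.
#' @return A [pseudo_ipd()] with exactly `risk$n_risk[1]` records.
#' @references Guyot et al. (2012) BMC Medical Research Methodology 12:9.
#' @export
reconstruct_pseudo_ipd <- function(curve, risk) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(risk, "risk_table"))
  t_s <- curve$points$time
  s <- curve$points$survival
  n_t <- length(t_s)
  if (t_s[1L] > min(risk$time))
    stop("risk table must not start before the first digitized point")

  # Risk intervals are right-closed: a digitized drop at exactly a
  # risk-table time reflects events that occurred before it, so that point
  # belongs to the preceding interval and the published at-risk count is
  # compared after its events are deducted. lower[i] indexes the first
  # digitized point strictly after risk time i (the first interval starts
  # at the first point); a virtual index n_t + 1 means "past the last
  # digitized point".
  n_int <- nrow(risk)
  lower <- vapply(risk$time, function(tt) {
    k <- which(t_s > tt + 1e-9)
    if (length(k)) k[1L] else n_t + 1L
  }, integer(1))
  lower[1L] <- 1L
  boundary_t <- c(risk$time[-1L], max(t_s, risk$time[n_int]))

  n_risk <- risk$n_risk
  n_hat <- rep(NA_real_, n_t + 1L)
  n_hat[1L] <- n_risk[1L]
  d <- integer(n_t)          # events at each digitized point
  cen <- integer(n_t)        # censorings binned to the preceding point
  cen_times <- vector("list", n_int)
  km_hat <- rep(1, n_t)
  last_i <- 1L               # index of last point with an event

  upper_of <- function(i) {
    up <- if (i < n_int) lower[i + 1L] - 1L else n_t
    min(up, n_t)
  }

  process_interval <- function(i, n_censor) {
    # Distribute n_censor censorings uniformly over the interval, then walk
    # the digitized points computing rounded event counts from the KM ratio.
    lo <- lower[i]; up <- upper_of(i)
    ct <- numeric(0)
    if (n_censor > 0) {
      a <- t_s[lo]; b <- boundary_t[min(i, length(boundary_t))]
      ct <- a + seq_len(n_censor) * (b - a) / (n_censor + 1)
    }
    cen_loc <- integer(n_t)
    for (tc in ct) {
      k <- max(which(t_s <= tc + 1e-12))
      cen_loc[k] <- cen_loc[k] + 1L
    }
    nh <- n_hat; dd <- d; km <- km_hat; last <- last_i
    if (lo <= n_t) {
      for (k in lo:up) {
        if (i == 1L && k == lo) {
          dd[k] <- 0L
          km[k] <- 1
        } else {
          km_last <- km[last]
          dd[k] <- if (km_last <= 0) 0L else round(nh[k] * (1 - s[k] / km_last))
          dd[k] <- max(0L, min(as.integer(dd[k]), as.integer(nh[k])))
          km[k] <- if (nh[k] > 0) km_last * (1 - dd[k] / nh[k]) else km[last]
        }
        nh[k + 1L] <- nh[k] - dd[k] - cen_loc[k]
        if (nh[k + 1L] < 0) nh[k + 1L] <- 0
        if (dd[k] > 0) last <- k
      }
    }
    list(n_hat = nh, d = dd, cen_loc = cen_loc, km = km, last = last, ct = ct)
  }

  for (i in seq_len(n_int)) {
    lo <- lower[i]
    if (lo > n_t) break
    target_idx <- if (i < n_int) lower[i + 1L] else n_t + 1L
    target_n <- if (i < n_int) n_risk[i + 1L] else NA
    # First guess for the interval's censor count (0 in the last interval:
    # leftover patients are censored administratively at the end).
    n_censor <- if (i < n_int)
      round(n_hat[lo] * (if (target_idx <= n_t) s[target_idx] else s[n_t]) /
              max(s[lo], .Machine$double.eps) - target_n)
    else 0
    n_censor <- max(0, n_censor)
    iter <- 0L
    repeat {
      res <- process_interval(i, n_censor)
      if (i == n_int) break
      gap <- res$n_hat[target_idx] - target_n
      iter <- iter + 1L
      if (gap == 0 || (gap < 0 && n_censor <= 0) || iter > 200L) break
      n_censor <- max(0, n_censor + gap)
      if (n_censor > n_hat[lo]) { n_censor <- n_hat[lo]; res <- process_interval(i, n_censor); break }
    }
    n_hat <- res$n_hat; d <- res$d; km_hat <- res$km; last_i <- res$last
    cen[seq_len(n_t)] <- cen[seq_len(n_t)] + res$cen_loc
    cen_times[[i]] <- res$ct
    # If the published count exceeds what remains, trust the reconstruction.
    if (i < n_int && n_hat[target_idx] < n_risk[i + 1L])
      n_risk[i + 1L] <- n_hat[target_idx]
  }

  times <- c(rep(t_s, d), unlist(cen_times))
  events <- c(rep(1L, sum(d)), rep(0L, length(unlist(cen_times))))
  leftover <- risk$n_risk[1L] - length(times)
  if (leftover > 0) {
    times <- c(times, rep(max(t_s), leftover))
    events <- c(events, rep(0L, leftover))
  } else if (leftover < 0) {
    stop("reconstruction produced more records than patients enrolled")
  }
  pseudo_ipd(times, events, arm = curve$arm)
}

#' Kaplan-Meier estimate from pseudo individual-patient data
#'
#' Product-limit estimate computed with [survival::survfit()]; returned as a
#' [digitized_curve()] whose points are `(0, 1)` followed by the step values
#' at each event time, so that a reconstruction can be validated round-trip
#' against the curve it came from.
#'
#' @param ipd A [pseudo_ipd()] with at least one record.
#' @return A [digitized_curve()].
#' @export
km_estimate <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  if (nrow(ipd) < 1L) stop("at least one record is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  tt <- fit$time[keep]
  ss <- fit$surv[keep]
  if (length(tt) == 0 || tt[1L] > 0) {
    tt <- c(0, tt); ss <- c(1, ss)
  }
  digitized_curve(tt, ss, arm = attr(ipd, "arm"), repair = FALSE)
}

#' Evaluate a digitized (step) curve at arbitrary times
#'
#' Left-continuous step interpolation: the survival at `t` is the value at
#' the last digitized point not exceeding `t` (1 before the first point).
#'
#' @param curve A [digitized_curve()].
#' @param t Times in months.
#' @return Survival probabilities.
#' @export
curve_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "digitized_curve"))
  stats::approx(curve$points$time, curve$points$survival, xout = t,
                method = "constant", yleft = 1,
                yright = min(curve$points$survival), rule = 2)$y
}

#' Read/write the curve and risk-table CSV dialects
#'
#' `read_digitized_curve()` expects a header `time,survival`;
#' `read_risk_table()` expects `time,n_risk`.
#'
#' @param path File path.
#' @param arm Arm label attached to the curve.
#' @return The parsed object.
#' @export
read_digitized_curve <- function(path, arm = "") {
  df <- utils::read.csv(path)
  if (!all(c("time", "survival") %in% names(df)))
    stop("curve CSV must have columns 'time' and 'survival'")
  digitized_curve(df$time, df$survival, arm = arm)
}

#' @rdname read_digitized_curve
#' @export
read_risk_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "n_risk") %in% names(df)))
    stop("risk table CSV must have columns 'time' and 'n_risk'")
  risk_table(df$time, df$n_risk)
}

#' @rdname read_digitized_curve
#' @param curve A [digitized_curve()] to write.
#' @export
write_digitized_curve <- function(curve, path) {
  utils::write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_digitized_curve
#' @param risk A [risk_table()] to write.
#' @export
write_risk_table <- function(risk, path) {
  utils::write.csv(as.data.frame(risk), path, row.names = FALSE)
  invisible(path)
}
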