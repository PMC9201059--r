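#' Pseudo individual-patient data
#'
#' @param time Event or censoring times in months (non-negative).
#' @param event Event indicators (1 = event, 0 = censored).
#'
#' @return A data.frame of class `pseudo_ipd` with columns `time`, `event`.
#' @export
pseudo_ipd <- function(time, event) {
  if (length(time) != length(event) || length(time) == 0L)
    domain_error("time and event must be nonempty vectors of equal length")
  if (any(time < 0)) domain_error("times must be non-negative")
  if (!all(event %in% c(0, 1))) domain_error("event must be 0 or 1")
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            class = c("pseudo_ipd", "data.frame"))
}

#' Digitized Kaplan-Meier curve input
#'
#' Container for published-curve coordinates plus the numbers-at-risk
#' table, the inputs of the pseudo-IPD reconstruction. Coordinates arrive
#' as plain numbers (e.g. from a digitization CSV); no image handling.
#'
#' @param times Curve time coordinates in months, non-decreasing.
#' @param survival Survival probabilities at `times`, non-increasing,
#'   in [0, 1].
#' @param risk_times Times of the numbers-at-risk table.
#' @param n_at_risk Numbers at risk at `risk_times`, non-increasing.
#'
#' @return An object of class `km_curve_input`.
#' @export
km_curve_input <- function(times, survival, risk_times, n_at_risk) {
  if (length(times) != length(survival) || length(times) == 0L)
    validation_error("times and survival must be nonempty and of equal length")
  if (is.unsorted(times)) validation_error("times must be non-decreasing")
  if (any(survival < 0 | survival > 1))
    validation_error("survival values must lie in [0, 1]")
  if (any(diff(survival) > 1e-9))
    validation_error("survival must be non-increasing")
  if (length(risk_times) != length(n_at_risk) || length(risk_times) == 0L)
    validation_error("risk_times and n_at_risk must be nonempty and of equal length")
  if (is.unsorted(risk_times)) validation_error("risk_times must be non-decreasing")
  if (any(diff(n_at_risk) > 0))
    validation_error("n_at_risk must be non-increasing")
  if (any(n_at_risk < 0)) validation_error("n_at_risk must be non-negative")
  structure(list(times = as.numeric(times), survival = as.numeric(survival),
                 risk_times = as.numeric(risk_times),
                 n_at_risk = as.integer(round(n_at_risk))),
            class = "km_curve_input")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param ipd A [pseudo_ipd()] (or data.frame with `time` and `event`).
#'
#' @return A `km_curve`: data.frame with one row per distinct time at
#'   which something happens, columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (the product-limit estimate just after
#'   `time`), with attribute `n` (number of subjects).
#' @export
#'
#' @examples
#' km_estimate(pseudo_ipd(c(1, 2, 3, 4), c(1, 0, 1, 0)))
km_estimate <- function(ipd) {
  if (is.null(ipd) || nrow(ipd) == 0L) domain_error("empty survival data")
  time <- ipd$time
  event <- ipd$event
  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk[i] <- sum(time >= t)
    n_event[i] <- sum(time == t & event == 1)
    n_censor[i] <- sum(time == t & event == 0)
    if (n_event[i] > 0) s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            n = n, class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation; 1 before the first event.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param t Times (vectorized).
#'
#' @return Survival probabilities at `t`.
#' @export
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Median of a Kaplan-Meier curve
#'
#' Smallest observed time at which the estimate drops to 0.5 or below,
#' NA if it never does.
#'
#' @param km A `km_curve`.
#' @return Median time in months, or NA.
#' @export
km_median <- function(km) {
  i <- which(km$survival <= 0.5)
  if (length(i)) km$time[i[1]] else NA_real_
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Interval-wise allocation in the style of the standard published-curve
#' reconstruction algorithms: within each numbers-at-risk interval, event
#' counts are inferred from the relative drops of the published curve
#' (tracked against the running reconstructed estimate, so rounding does
#' not drift) and censorings are distributed uniformly over the interval,
#' iterating the interval's censor count until the implied number at risk
#' matches the published risk table. Subjects still at risk after the
#' last curve coordinate are administratively censored there. The
#' procedure is deterministic.
#'
#' @param curve A [km_curve_input()].
#'
#' @return A [pseudo_ipd()] with one record per subject in the initial
#'   risk set; re-running [km_estimate()] on it reproduces the input
#'   survival on the input time grid up to integer-count rounding.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "km_curve_input"))
  times <- curve$times
  surv <- curve$survival
  if (times[1] > 0) {            # anchor the curve at (0, 1)
    times <- c(0, times)
    surv <- c(1, surv)
  }
  rt <- curve$risk_times
  nar <- curve$n_at_risk
  t_max <- max(times)
  # interval boundaries: risk-table times, closing with the end of follow-up
  bounds <- sort(unique(c(0, rt, t_max)))
  if (length(bounds) == 1L) bounds <- c(0, bounds)
  out_time <- numeric(0)
  out_event <- integer(0)
  n_cur <- nar[1]
  s_hat <- 1
  for (j in seq_len(length(bounds) - 1L)) {
    lo <- bounds[j]
    hi <- bounds[j + 1L]
    last_interval <- j == length(bounds) - 1L
    n_target <- if (last_interval) NA_integer_ else {
      k <- match(hi, rt)
      if (is.na(k)) NA_integer_ else nar[k]
    }
    step_idx <- which(times > lo & times <= hi)
    # published survival at each step time, and at interval entry
    s_steps <- surv[step_idx]
    t_steps <- times[step_idx]

    run_interval <- function(c_guess) {
      cens <- if (c_guess > 0)
        lo + (seq_len(c_guess) - 0.5) / c_guess * (hi - lo) else numeric(0)
      ev_t <- numeric(0); ev_d <- integer(0)
      n <- n_cur; s <- s_hat
      ci <- 1
      for (m in seq_along(t_steps)) {
        # a drop observed at coordinate t happened somewhere since the
        # previous coordinate; the midpoint is the unbiased placement for
        # curves digitized on a regular grid
        prev <- if (m > 1) t_steps[m - 1] else lo
        t_place <- (prev + t_steps[m]) / 2
        while (ci <= length(cens) && cens[ci] < t_place) {
          n <- n - 1L; ci <- ci + 1L
        }
        d <- if (n > 0 && s > 0) round(n * (1 - s_steps[m] / s)) else 0
        d <- max(0L, min(as.integer(d), n))
        if (d > 0) {
          s <- s * (1 - d / n)
          ev_t <- c(ev_t, t_place); ev_d <- c(ev_d, d)
          n <- n - d
        }
      }
      n_cens_left <- length(cens) - ci + 1L
      n <- n - n_cens_left
      list(n_end = n, s_end = s, cens = cens, ev_t = ev_t, ev_d = ev_d)
    }

    if (is.na(n_target)) {
      res <- run_interval(0L)
      c_final <- 0L
    } else {
      c_guess <- 0L
      res <- run_interval(c_guess)
      for (it in seq_len(100)) {
        delta <- res$n_end - n_target
        if (delta == 0L) break
        if (delta < 0L && c_guess == 0L) break  # risk table inconsistent with drops
        c_guess <- max(0L, min(n_cur, c_guess + delta))
        res <- run_interval(c_guess)
      }
      c_final <- c_guess
    }
    out_time <- c(out_time, rep(res$ev_t, res$ev_d), res$cens)
    out_event <- c(out_event, rep(1L, sum(res$ev_d)),
                   rep(0L, length(res$cens)))
    n_cur <- res$n_end
    s_hat <- res$s_end
  }
  # administrative censoring of survivors at the end of follow-up
  if (n_cur > 0) {
    out_time <- c(out_time, rep(t_max, n_cur))
    out_event <- c(out_event, rep(0L, n_cur))
  }
  ord <- order(out_time, out_event)
  pseudo_ipd(out_time[ord], out_event[ord])
}

#' Maximum-likelihood parametric survival fit
#'
#' Fits an exponential or Weibull law to right-censored time-to-event
#' data. The exponential rate has the closed form events / total
#' follow-up time; the Weibull shape is found by maximizing the profile
#' log-likelihood (the scale is profiled out analytically for fixed
#' shape).
#'
#' @param ipd A [pseudo_ipd()] (or data.frame with `time`, `event`).
#' @param family `"exponential"` or `"weibull"`.
#'
#' @return A [survival_curve()].
#' @export
#'
#' @examples
#' fit_parametric(pseudo_ipd(c(2, 3, 4), c(1, 1, 1)), "exponential")
fit_parametric <- function(ipd, family = c("exponential", "weibull")) {
  family <- match.arg(family)
  d <- sum(ipd$event == 1)
  if (nrow(ipd) == 0L) domain_error("empty survival data")
  if (d == 0L)
    mbcea_error("parametric fit requires at least one event", "mbcea_fit_error")
  if (family == "exponential") {
    rate <- d / sum(ipd$time)
    return(survival_curve(scale = 1 / rate, shape = 1))
  }
  t_all <- pmax(ipd$time, 1e-12)
  t_ev <- t_all[ipd$event == 1]
  prof_ll <- function(log_k) {
    k <- exp(log_k)
    a <- sum(t_all^k) / d           # lambda^k at the profile optimum
    d * log(k) - d * log(a) + (k - 1) * sum(log(t_ev)) - d
  }
  opt <- optimize(prof_ll, interval = log(c(0.05, 20)), maximum = TRUE)
  k <- exp(opt$maximum)
  lambda <- (sum(t_all^k) / d)^(1 / k)
  survival_curve(scale = lambda, shape = k,
                 family = if (abs(k - 1) < 1e-12) "exponential" else "weibull")
}
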