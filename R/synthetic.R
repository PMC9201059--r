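#' Synthetic two-arm trial specification
#'
#' Describes the data-generating process the analysis assumes: per-arm
#' Weibull (default exponential) event-free survival at the stated
#' median, overall survival generated as EFS plus an exponential
#' post-progression survival whose rate is solved numerically so the
#' marginal OS median matches the stated value (which guarantees the
#' per-patient coherence OS >= EFS the partitioned model relies on), and
#' administrative censoring at the end of follow-up.
#'
#' @param n_per_arm Patients per arm (default 50, a phase-II
#'   screening-trial scale).
#' @param efs_median,os_median Median EFS/OS in months; either scalars
#'   (single arm) or equal-length vectors with `arm_names` labels.
#'   Defaults are the base-case medians 9/6 (EFS) and 19/13 (OS).
#' @param shape Weibull shape of the EFS law (default 1).
#' @param admin_censor_time Administrative censoring time in months
#'   (default 24).
#' @param seed Integer RNG seed.
#' @param arm_names Arm labels (default `tib`, `ti` for two arms).
#'
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_per_arm = 50,
                       efs_median = c(9, 6), os_median = c(19, 13),
                       shape = 1, admin_censor_time = 24, seed = 1L,
                       arm_names = NULL) {
  if (length(efs_median) != length(os_median))
    validation_error("efs_median and os_median must have equal length")
  if (is.null(arm_names))
    arm_names <- if (length(efs_median) == 2L) c("tib", "ti")
                 else paste0("arm", seq_along(efs_median))
  if (n_per_arm < 1) validation_error("invariant violated: n_per_arm >= 1")
  if (any(efs_median <= 0) || any(os_median <= 0))
    validation_error("invariant violated: medians > 0")
  if (any(efs_median > os_median))
    validation_error("invariant violated: efs_median <= os_median")
  if (admin_censor_time <= 0)
    validation_error("invariant violated: admin_censor_time > 0")
  if (shape <= 0) validation_error("invariant violated: shape > 0")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 efs_median = efs_median, os_median = os_median,
                 shape = shape, admin_censor_time = admin_censor_time,
                 seed = as.integer(seed), arm_names = arm_names),
            class = "trial_spec")
}

# Post-progression survival rate such that median(EFS + PPS) = os_median,
# with EFS ~ Weibull(median efs_median, shape) and PPS ~ Exp(rate).
solve_pps_rate <- function(efs_median, os_median, shape) {
  if (os_median <= efs_median * (1 + 1e-12)) return(Inf)  # no PPS needed
  scale <- efs_median / log(2)^(1 / shape)
  s_sum <- function(t, rate) {
    # P(EFS + PPS > t); closed-form hypoexponential for shape 1
    if (shape == 1) {
      a <- 1 / scale
      if (abs(a - rate) < 1e-10 * a) return((1 + a * t) * exp(-a * t))
      return((rate * exp(-a * t) - a * exp(-rate * t)) / (rate - a))
    }
    integrand <- function(s)
      (shape / scale) * (s / scale)^(shape - 1) * exp(-(s / scale)^shape) *
        exp(-rate * (t - s))
    exp(-(t / scale)^shape) +
      integrate(integrand, 0, t, rel.tol = 1e-8)$value
  }
  median_of <- function(rate) {
    # S(upper) < 0.25 is guaranteed when both halves exceed their 0.25 points
    upper <- 2 * max(scale * log(4)^(1 / shape), log(4) / rate) + 1
    uniroot(function(t) s_sum(t, rate) - 0.5,
            lower = 0, upper = upper, tol = 1e-10)$root
  }
  uniroot(function(r) median_of(r) - os_median,
          lower = 1e-8, upper = 1000 / (os_median - efs_median),
          tol = 1e-12)$root
}

#' Simulate a synthetic trial
#'
#' Draws per-patient EFS and OS times according to a [trial_spec()] and
#' applies administrative censoring. OS is EFS plus an exponential
#' post-progression time, so OS >= EFS for every patient.
#'
#' @param spec A [trial_spec()].
#'
#' @return A data.frame with columns `arm`, `efs_time`, `efs_event`,
#'   `os_time`, `os_event`; times in months, events 1/0.
#' @export
#'
#' @examples
#' head(simulate_trial(trial_spec(n_per_arm = 10, seed = 7)))
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  cens <- spec$admin_censor_time
  out <- lapply(seq_along(spec$arm_names), function(k) {
    n <- spec$n_per_arm
    scale <- spec$efs_median[k] / log(2)^(1 / spec$shape)
    efs <- scale * (-log(runif(n)))^(1 / spec$shape)
    rate <- solve_pps_rate(spec$efs_median[k], spec$os_median[k], spec$shape)
    pps <- if (is.infinite(rate)) rep(0, n) else -log(runif(n)) / rate
    os <- efs + pps
    data.frame(arm = spec$arm_names[k],
               efs_time = pmin(efs, cens), efs_event = as.integer(efs <= cens),
               os_time = pmin(os, cens), os_event = as.integer(os <= cens))
  })
  do.call(rbind, out)
}

#' Digitized-curve inputs from simulated trial records
#'
#' Computes the Kaplan-Meier estimate of each endpoint, samples it on a
#' regular time grid and attaches the numbers at risk at the grid times
#' -- the same shape of input a digitized published curve plus risk
#' table provides, ready for [reconstruct_ipd()].
#'
#' @param records Trial records from [simulate_trial()] (one arm, or use
#'   the `arm` column to subset; if several arms are present a named
#'   list per arm is returned).
#' @param grid_step Grid spacing in months (default 0.5).
#'
#' @return For a single arm, a list with elements `efs` and `os`, each a
#'   [km_curve_input()]; for several arms, a named list of such lists.
#' @export
km_inputs_from_trial <- function(records, grid_step = 0.5) {
  if (is.null(records) || nrow(records) == 0L)
    domain_error("empty trial records")
  arms <- unique(records$arm)
  if (length(arms) > 1L) {
    out <- lapply(arms, function(a)
      km_inputs_from_trial(records[records$arm == a, , drop = FALSE], grid_step))
    names(out) <- arms
    return(out)
  }
  one <- function(time, event) {
    km <- km_estimate(data.frame(time = time, event = event))
    t_max <- max(time)
    grid <- seq(0, t_max, by = grid_step)
    if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
    km_curve_input(times = grid,
                   survival = km_survival_at(km, grid),
                   risk_times = grid,
                   n_at_risk = vapply(grid, function(g) sum(time >= g), numeric(1)))
  }
  list(efs = one(records$efs_time, records$efs_event),
       os = one(records$os_time, records$os_event))
}
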