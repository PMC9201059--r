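#' Parametric survival curve
#'
#' A Weibull time-to-event law S(t) = exp(-(t/scale)^shape), with the
#' exponential as the shape = 1 special case. Time is measured in months.
#'
#' @param scale Scale parameter in months (positive).
#' @param shape Shape parameter (positive; 1 gives the exponential).
#' @param family Optional family label; inferred from `shape` when omitted.
#'
#' @return An object of class `survival_curve` with fields `family`,
#'   `scale`, `shape`.
#' @export
survival_curve <- function(scale, shape = 1, family = NULL) {
  scale <- check_number(scale, "scale")
  shape <- check_number(shape, "shape")
  if (scale <= 0) domain_error("scale must be positive")
  if (shape <= 0) domain_error("shape must be positive")
  if (is.null(family)) family <- if (shape == 1) "exponential" else "weibull"
  family <- match.arg(family, c("exponential", "weibull"))
  if (family == "exponential" && shape != 1)
    domain_error("exponential curves require shape = 1")
  structure(list(family = family, scale = scale, shape = shape),
            class = "survival_curve")
}

#' Survival curve from a reported median
#'
#' Converts a reported median time-to-event into curve parameters so that
#' S(median) = 0.5 exactly: scale = median / log(2)^(1/shape). The
#' published analysis reports only medians, so the identifiable base case
#' is the one-parameter exponential (shape 1); a different shape can be
#' supplied as a structural assumption.
#'
#' @param median Median time-to-event in months (positive).
#' @param shape Shape parameter (positive, default 1).
#'
#' @return A [survival_curve()].
#' @export
#'
#' @examples
#' curve_from_median(9)         # exponential, hazard log(2)/9 per month
#' curve_from_median(19, 1.5)   # Weibull alternative
curve_from_median <- function(median, shape = 1) {
  median <- check_number(median, "median")
  shape <- check_number(shape, "shape")
  if (median <= 0) domain_error("median must be positive")
  if (shape <= 0) domain_error("shape must be positive")
  survival_curve(scale = median / log(2)^(1 / shape), shape = shape)
}

#' Monthly hazard rate of an exponential curve
#'
#' @param curve A shape-1 [survival_curve()].
#' @return The constant hazard rate per month, 1/scale.
#' @export
hazard_rate <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  if (curve$shape != 1)
    domain_error("a constant hazard rate only exists for shape = 1")
  1 / curve$scale
}

#' Survival probability at time t
#'
#' @param curve A [survival_curve()].
#' @param t Time in months (non-negative; vectorized).
#'
#' @return S(t) = exp(-(t/scale)^shape), in [0, 1].
#' @export
#'
#' @examples
#' survival_at(curve_from_median(19), 120) # 2^(-120/19)
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(t) || any(is.na(t))) domain_error("t must be numeric")
  if (any(t < 0)) domain_error("t must be non-negative")
  exp(-(t / curve$scale)^curve$shape)
}

#' Per-cycle event probability
#'
#' Conditional probability of the event during cycle `cycle` given
#' event-free at its start: 1 - S(cycle + 1) / S(cycle), with the cycle
#' spanning months [cycle, cycle + 1). For shape 1 this is constant in
#' `cycle` (memorylessness).
#'
#' @param curve A [survival_curve()].
#' @param cycle Cycle index (non-negative integer; vectorized).
#'
#' @return Probability in [0, 1].
#' @export
#'
#' @examples
#' cycle_event_prob(curve_from_median(9), 0) # 1 - exp(-log(2)/9)
cycle_event_prob <- function(curve, cycle) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(cycle) || any(is.na(cycle)) || any(cycle < 0))
    domain_error("cycle must be a non-negative index")
  s0 <- survival_at(curve, cycle)
  if (any(s0 <= 0))
    mbcea_error("event probability undefined: no survivors at cycle start",
                "mbcea_degenerate_error")
  pmin(pmax(1 - survival_at(curve, cycle + 1) / s0, 0), 1)
}

#' Partitioned-survival state membership
#'
#' Cohort fractions in the three health states at the start of each cycle,
#' derived directly from the event-free survival (EFS) and overall
#' survival (OS) curves: the event-free fraction is S_EFS(t), the dead
#' fraction 1 - S_OS(t), and progressed disease the area between the
#' curves, S_OS(t) - S_EFS(t). If the EFS curve crosses above the OS curve
#' the progressed-disease fraction is floored at 0 and the event-free
#' fraction truncated to S_OS(t), preserving the unit simplex.
#'
#' @param efs_curve,os_curve [survival_curve()] objects for EFS and OS.
#' @param cycle Cycle index (non-negative; vectorized).
#'
#' @return A data.frame with columns `cycle`, `efs`, `pd`, `dead`, each
#'   row summing to 1.
#' @export
#'
#' @examples
#' partition_membership(curve_from_median(9), curve_from_median(19), 0:3)
partition_membership <- function(efs_curve, os_curve, cycle) {
  s_efs <- survival_at(efs_curve, cycle)
  s_os <- survival_at(os_curve, cycle)
  efs <- pmin(s_efs, s_os)
  pd <- s_os - efs
  dead <- 1 - s_os
  data.frame(cycle = cycle, efs = efs, pd = pd, dead = dead)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("%s survival curve: scale %.4f months, shape %.4f (median %.4f)\n",
              x$family, x$scale, x$shape, x$scale * log(2)^(1 / x$shape)))
  invisible(x)
}
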