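#' Per-cycle discount factor
#'
#' Discounting at an annual rate applied to monthly cycles:
#' (1 + rate)^(-cycle / 12).
#'
#' @param annual_rate Annual discount rate (> -1).
#' @param cycle Cycle index in months (non-negative; vectorized).
#'
#' @return Discount multiplier in (0, 1] for non-negative rates.
#' @export
#'
#' @examples
#' discount_factor(0.03, 12) # one-year discount, 1/1.03
discount_factor <- function(annual_rate, cycle) {
  if (!is.numeric(annual_rate) || length(annual_rate) != 1L || is.na(annual_rate) ||
      annual_rate <= -1)
    domain_error("annual_rate must be a single number > -1")
  if (!is.numeric(cycle) || any(is.na(cycle)) || any(cycle < 0))
    domain_error("cycle must be non-negative")
  (1 + annual_rate)^(-cycle / 12)
}

#' Cost of one cycle in a given health state
#'
#' Event-free patients within the treatment cap (cycle <
#' `max_treatment_cycles`) accrue drug, tests, hospitalization and
#' adverse-event costs; beyond the cap only tests and hospitalization
#' continue. Progressed patients accrue the second-line treatment cost.
#' Death costs nothing.
#'
#' @param arm An [arm_parameters()] object.
#' @param state One of `"efs"`, `"pd"`, `"dead"`.
#' @param cycle Cycle index (non-negative; vectorized).
#'
#' @return Cost in USD for one cohort member spending the cycle in `state`.
#' @export
#'
#' @examples
#' cfg <- load_config(system.file("extdata", "table1.yaml", package = "mbcea"))
#' state_cycle_cost(cfg$arms$tib, "efs", 3) # on-treatment EFS cycle
state_cycle_cost <- function(arm, state, cycle) {
  stopifnot(inherits(arm, "arm_parameters"))
  if (!is.numeric(cycle) || any(is.na(cycle)) || any(cycle < 0))
    domain_error("cycle must be non-negative")
  if (length(state) != 1L || !state %in% c("efs", "pd", "dead"))
    domain_error(sprintf("unknown health state: %s",
                         paste(state, collapse = ", ")))
  switch(state,
    efs = ifelse(cycle < arm$max_treatment_cycles,
                 arm$drug_cost_per_cycle + arm$tests_cost_per_cycle +
                   arm$hospitalization_cost_per_cycle + arm$ae_cost_per_cycle,
                 arm$tests_cost_per_cycle + arm$hospitalization_cost_per_cycle),
    pd = rep(arm$second_line_cost_per_cycle, length(cycle)),
    dead = rep(0, length(cycle))
  )
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Attaches per-cycle costs and utilities to the state occupancy of a
#' Markov trace under the state-at-entry convention: the occupancy at the
#' start of cycle k earns that cycle's cost and utility, discounted by
#' [discount_factor()] at k months. Per-cycle QALY increments are the
#' annual utility weight divided by 12. The optional half-cycle correction
#' replaces each cycle's occupancy with the average of its start and end
#' occupancy.
#'
#' @param trace A `markov_trace` from [run_trace()] (or a data.frame with
#'   columns `cycle`, `efs`, `pd`, `dead`).
#' @param arm An [arm_parameters()] object.
#' @param utilities A [utility_set()] object.
#' @param settings An [economic_settings()] object.
#' @param half_cycle Apply the half-cycle correction (default FALSE).
#'
#' @return An `arm_outcome`: list with per-state cost totals `c_efs`,
#'   `c_pd`, per-state QALY totals `u_efs_total`, `u_pd_total`,
#'   `total_cost`, `total_qaly` and the average cost-effectiveness ratio
#'   `ce_ratio` (USD/QALY).
#' @export
accumulate <- function(trace, arm, utilities, settings, half_cycle = FALSE) {
  stopifnot(inherits(arm, "arm_parameters"), inherits(utilities, "utility_set"),
            inherits(settings, "economic_settings"))
  cyc <- trace$cycle
  occ_efs <- trace$efs
  occ_pd <- trace$pd
  if (half_cycle) {
    n <- length(cyc)
    avg <- function(x) (x + c(x[-1], x[n])) / 2
    occ_efs <- avg(occ_efs)
    occ_pd <- avg(occ_pd)
  }
  disc <- discount_factor(settings$annual_discount_rate, cyc)
  c_efs <- sum(occ_efs * state_cycle_cost(arm, "efs", cyc) * disc)
  c_pd <- sum(occ_pd * state_cycle_cost(arm, "pd", cyc) * disc)
  u_efs_total <- sum(occ_efs * utilities$u_efs / 12 * disc)
  u_pd_total <- sum(occ_pd * utilities$u_pd / 12 * disc)
  total_cost <- c_efs + c_pd
  total_qaly <- u_efs_total + u_pd_total
  structure(list(
    name = arm$name,
    c_efs = c_efs, c_pd = c_pd,
    u_efs_total = u_efs_total, u_pd_total = u_pd_total,
    total_cost = total_cost, total_qaly = total_qaly,
    ce_ratio = if (total_qaly > 0) total_cost / total_qaly else NA_real_
  ), class = "arm_outcome")
}

#' Construct an arm outcome from known totals
#'
#' Convenience constructor used when per-arm totals are given directly
#' (e.g. published results) rather than accumulated from a trace.
#'
#' @param total_cost,total_qaly Totals in USD and QALYs.
#' @param c_efs,c_pd,u_efs_total,u_pd_total Optional per-state breakdown;
#'   defaults attribute everything to the event-free state.
#' @param name Arm label.
#'
#' @return An `arm_outcome`.
#' @export
arm_outcome <- function(total_cost, total_qaly,
                        c_efs = total_cost, c_pd = total_cost - c_efs,
                        u_efs_total = total_qaly,
                        u_pd_total = total_qaly - u_efs_total,
                        name = "") {
  structure(list(
    name = name, c_efs = c_efs, c_pd = c_pd,
    u_efs_total = u_efs_total, u_pd_total = u_pd_total,
    total_cost = total_cost, total_qaly = total_qaly,
    ce_ratio = if (total_qaly > 0) total_cost / total_qaly else NA_real_
  ), class = "arm_outcome")
}

#' Incremental cost-effectiveness of two arms
#'
#' Incremental cost and QALYs are intervention minus comparator; the ICER
#' is their ratio when the incremental QALY is nonzero. Strict dominance
#' (cheaper and more effective, or dearer and less effective) is flagged
#' and no ratio is reported in that case, nor when the incremental QALY
#' is zero.
#'
#' @param intervention,comparator `arm_outcome` objects.
#'
#' @return A `cea_result`: list with both outcomes, `incremental_cost`,
#'   `incremental_qaly`, `icer` (NA when undefined or dominated) and
#'   `dominance` (one of `"none"`, `"intervention_dominant"`,
#'   `"intervention_dominated"`, `"undefined"`).
#' @export
#'
#' @examples
#' compute_icer(arm_outcome(27603.420, 1.147), arm_outcome(8786.403, 0.867))
compute_icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "arm_outcome"),
            inherits(comparator, "arm_outcome"))
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  if (dq == 0) {
    dominance <- "undefined"
    icer <- NA_real_
  } else if (dc < 0 && dq > 0) {
    dominance <- "intervention_dominant"
    icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    dominance <- "intervention_dominated"
    icer <- NA_real_
  } else {
    dominance <- "none"
    icer <- dc / dq
  }
  structure(list(
    intervention = intervention, comparator = comparator,
    incremental_cost = dc, incremental_qaly = dq,
    icer = icer, dominance = dominance
  ), class = "cea_result")
}

#' Run the base-case analysis for a configuration
#'
#' Builds the survival curves from the configured medians, runs the
#' Markov trace for each arm, accumulates discounted costs and QALYs and
#' computes the incremental result (intervention `tib` vs comparator
#' `ti`).
#'
#' @param config A `cea_config` from [load_config()].
#' @param shape Weibull shape for both curves (default 1, exponential).
#' @param half_cycle Apply the half-cycle correction (default FALSE).
#'
#' @return A list with elements `result` (a `cea_result`), `traces`
#'   (named list of `markov_trace` per arm) and `icer` (numeric shortcut).
#' @export
#'
#' @examples
#' cfg <- load_config(system.file("extdata", "table1.yaml", package = "mbcea"))
#' run_base_case(cfg)$icer
run_base_case <- function(config, shape = 1, half_cycle = FALSE) {
  stopifnot(inherits(config, "cea_config"))
  eval_arm <- function(arm) {
    efs <- curve_from_median(arm$median_efs, shape)
    os <- curve_from_median(arm$median_os, shape)
    trace <- run_trace(efs, os, config$settings)
    list(trace = trace,
         outcome = accumulate(trace, arm, config$utilities, config$settings,
                              half_cycle = half_cycle))
  }
  tib <- eval_arm(config$arms$tib)
  ti <- eval_arm(config$arms$ti)
  result <- compute_icer(tib$outcome, ti$outcome)
  list(result = result,
       traces = list(tib = tib$trace, ti = ti$trace),
       icer = result$icer)
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm %s: cost $%.3f (EFS %.3f + PD %.3f), QALY %.3f (EFS %.3f + PD %.3f), C/E %.3f\n",
              x$name, x$total_cost, x$c_efs, x$c_pd,
              x$total_qaly, x$u_efs_total, x$u_pd_total, x$ce_ratio))
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  print(x$intervention)
  print(x$comparator)
  cat(sprintf("Incremental: cost $%.3f, QALY %.3f, ICER %s, dominance %s\n",
              x$incremental_cost, x$incremental_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("$%.3f/QALY", x$icer),
              x$dominance))
  invisible(x)
}
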