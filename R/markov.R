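#' Run the Markov cohort trace
#'
#' Simulates the three-state cohort (event-free, progressed, dead) over
#' monthly cycles. The whole cohort enters event-free at cycle 0. The
#' trace stops at the earlier of the time horizon (`horizon_cycles`,
#' default 120 cycles = 10 years) and the first cycle at which the dead
#' fraction reaches `termination_fraction` (default 0.99).
#'
#' Two structural modes are available. The default, `"partitioned"`,
#' reads state occupancy directly off the EFS and OS curves
#' ([partition_membership()]), which is how occupancy is derived from
#' reported survival curves. The alternative `"transition"` mode builds
#' an explicit transition matrix per cycle: exits from the event-free
#' state at the EFS hazard are split between progression and death in
#' proportion to the OS death hazard, and the progressed state dies at
#' the OS hazard.
#'
#' @param efs_curve,os_curve [survival_curve()] objects.
#' @param settings An [economic_settings()] object.
#' @param method `"partitioned"` (default) or `"transition"`.
#'
#' @return A `markov_trace`: a data.frame with columns `cycle`, `efs`,
#'   `pd`, `dead` (one row per cycle from 0 to the terminal cycle) and
#'   attributes `terminal_cycle` and `termination_reason` (`"horizon"` or
#'   `"absorption"`).
#' @export
#'
#' @examples
#' tr <- run_trace(curve_from_median(9), curve_from_median(19),
#'                 economic_settings())
#' attr(tr, "termination_reason")
run_trace <- function(efs_curve, os_curve, settings = economic_settings(),
                      method = c("partitioned", "transition")) {
  stopifnot(inherits(efs_curve, "survival_curve"),
            inherits(os_curve, "survival_curve"),
            inherits(settings, "economic_settings"))
  method <- match.arg(method)
  horizon <- settings$horizon_cycles
  cycles <- 0:horizon

  if (method == "partitioned") {
    tr <- partition_membership(efs_curve, os_curve, cycles)
  } else {
    n <- length(cycles)
    efs <- pd <- dead <- numeric(n)
    efs[1] <- 1
    for (i in seq_len(n - 1L)) {
      t <- cycles[i]
      q_e <- if (survival_at(efs_curve, t) > 0) cycle_event_prob(efs_curve, t) else 1
      q_o <- if (survival_at(os_curve, t) > 0) cycle_event_prob(os_curve, t) else 1
      q_death_from_efs <- min(q_o, q_e)       # death share of EFS exits
      q_pd_from_efs <- q_e - q_death_from_efs
      efs[i + 1] <- efs[i] * (1 - q_e)
      pd[i + 1] <- pd[i] * (1 - q_o) + efs[i] * q_pd_from_efs
      dead[i + 1] <- dead[i] + pd[i] * q_o + efs[i] * q_death_from_efs
    }
    tr <- data.frame(cycle = cycles, efs = efs, pd = pd, dead = dead)
  }

  hit <- which(tr$dead >= settings$termination_fraction)
  if (length(hit) && (hit[1] - 1L) < horizon) {
    terminal <- hit[1] - 1L          # cycle index of the triggering row
    reason <- "absorption"
    tr <- tr[seq_len(hit[1]), , drop = FALSE]
  } else {
    terminal <- horizon
    reason <- "horizon"
  }
  rownames(tr) <- NULL
  structure(tr,
            terminal_cycle = as.integer(terminal),
            termination_reason = reason,
            class = c("markov_trace", "data.frame"))
}

#' Undiscounted person-time by state
#'
#' Sums state occupancy over the cycles of a trace; with monthly cycles
#' and state-at-entry accounting this is the person-months spent in each
#' state (a left-endpoint sum of the occupancy curve).
#'
#' @param trace A `markov_trace` (or data.frame with `efs`, `pd`, `dead`).
#' @return Named numeric vector `efs`, `pd`, `dead`, in person-months.
#' @export
person_time <- function(trace) {
  c(efs = sum(trace$efs), pd = sum(trace$pd), dead = sum(trace$dead))
}
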