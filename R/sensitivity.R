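# Named model parameters addressable by the sensitivity analyses.
# Arm-level names are "<arm>.<field>" with <arm> in {tib, ti}; drug
# components are "<arm>.drug.<component>"; "<arm>.efs_state_cost" is the
# composite on-treatment event-free state cost (drug + tests +
# hospitalization + AE), varied by scaling its components proportionally.

parse_param <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] %in% c("tib", "ti")) {
    if (length(parts) == 3L && parts[2] == "drug")
      return(list(kind = "component", arm = parts[1], comp = parts[3]))
    if (length(parts) == 2L)
      return(list(kind = "arm", arm = parts[1], field = parts[2]))
  } else if (length(parts) == 1L) {
    return(list(kind = "global", field = parts[1]))
  }
  validation_error(sprintf("unknown parameter name: %s", name))
}

arm_field_map <- c(median_efs = "median_efs", median_os = "median_os",
                   drug_cost = "drug_cost_per_cycle",
                   second_line_cost = "second_line_cost_per_cycle",
                   hospitalization_cost = "hospitalization_cost_per_cycle",
                   ae_cost = "ae_cost_per_cycle",
                   tests_cost = "tests_cost_per_cycle")

efs_state_cost_of <- function(arm) {
  arm$drug_cost_per_cycle + arm$tests_cost_per_cycle +
    arm$hospitalization_cost_per_cycle + arm$ae_cost_per_cycle
}

#' Read a named model parameter from a configuration
#'
#' @param config A `cea_config`.
#' @param name Parameter name (see [one_way_dsa()] for the naming scheme).
#' @return The parameter's base value.
#' @export
get_parameter <- function(config, name) {
  p <- parse_param(name)
  if (p$kind == "global") {
    switch(p$field,
      discount_rate = config$settings$annual_discount_rate,
      wtp_threshold = config$settings$wtp_threshold,
      u_efs = config$utilities$u_efs,
      u_pd = config$utilities$u_pd,
      validation_error(sprintf("unknown parameter name: %s", name)))
  } else if (p$kind == "component") {
    comp <- config$arms[[p$arm]]$drug_cost_components
    if (is.null(comp[[p$comp]]))
      validation_error(sprintf("arm '%s' has no drug component '%s'", p$arm, p$comp))
    comp[[p$comp]]
  } else if (p$field == "efs_state_cost") {
    efs_state_cost_of(config$arms[[p$arm]])
  } else {
    f <- arm_field_map[p$field]
    if (is.na(f)) validation_error(sprintf("unknown parameter name: %s", name))
    config$arms[[p$arm]][[f]]
  }
}

#' Set a named model parameter
#'
#' Returns a modified copy of the configuration. Setting a drug component
#' updates the arm's total drug cost; setting the composite
#' `<arm>.efs_state_cost` rescales its four components proportionally.
#' Values are assigned directly (the sensitivity analyses may explore
#' values outside the base-case invariants, e.g. a drawn EFS median above
#' the OS median, which the partitioned-survival clamping rule absorbs).
#'
#' @param config A `cea_config`.
#' @param name Parameter name.
#' @param value New value.
#' @return The modified `cea_config`.
#' @export
set_parameter <- function(config, name, value) {
  p <- parse_param(name)
  if (p$kind == "global") {
    switch(p$field,
      discount_rate = { config$settings$annual_discount_rate <- value },
      wtp_threshold = { config$settings$wtp_threshold <- value },
      u_efs = { config$utilities$u_efs <- value },
      u_pd = { config$utilities$u_pd <- value },
      validation_error(sprintf("unknown parameter name: %s", name)))
  } else if (p$kind == "component") {
    arm <- config$arms[[p$arm]]
    if (is.null(arm$drug_cost_components[[p$comp]]))
      validation_error(sprintf("arm '%s' has no drug component '%s'", p$arm, p$comp))
    arm$drug_cost_components[[p$comp]] <- value
    arm$drug_cost_per_cycle <- sum(unlist(arm$drug_cost_components))
    config$arms[[p$arm]] <- arm
  } else if (p$field == "efs_state_cost") {
    arm <- config$arms[[p$arm]]
    base <- efs_state_cost_of(arm)
    if (base <= 0) validation_error("cannot rescale a zero composite cost")
    f <- value / base
    arm$drug_cost_per_cycle <- arm$drug_cost_per_cycle * f
    arm$tests_cost_per_cycle <- arm$tests_cost_per_cycle * f
    arm$hospitalization_cost_per_cycle <- arm$hospitalization_cost_per_cycle * f
    arm$ae_cost_per_cycle <- arm$ae_cost_per_cycle * f
    if (!is.null(arm$drug_cost_components))
      arm$drug_cost_components <- lapply(arm$drug_cost_components, `*`, f)
    config$arms[[p$arm]] <- arm
  } else {
    f <- arm_field_map[p$field]
    if (is.na(f)) validation_error(sprintf("unknown parameter name: %s", name))
    config$arms[[p$arm]][[f]] <- value
  }
  config
}

eval_icer_at <- function(config, overrides = NULL, shape = 1) {
  if (length(overrides))
    for (nm in names(overrides))
      config <- set_parameter(config, nm, overrides[[nm]])
  run_base_case(config, shape = shape)$result
}

#' Default one-way sensitivity ranges
#'
#' Economic parameters at +/-20% of their base values (utility upper
#' bounds capped at 1), and the discount rate over 0-5%/year. The
#' survival medians are deliberately not part of the default tornado:
#' the deterministic analysis explores price and utility uncertainty
#' (drug prices vary across provincial procurement lists), while
#' uncertainty in the transition probabilities is explored by the
#' probabilistic analysis. Medians can still be added explicitly.
#'
#' @param config A `cea_config`.
#' @param rel Relative half-width of the default ranges (default 0.2).
#'
#' @return A data.frame with columns `parameter`, `low`, `high`.
#' @export
default_dsa_ranges <- function(config, rel = 0.2) {
  pars <- character(0)
  for (a in c("tib", "ti")) {
    pars <- c(pars, paste0(a, ".efs_state_cost"))
    comp <- config$arms[[a]]$drug_cost_components
    pars <- c(pars,
              if (!is.null(comp)) paste0(a, ".drug.", names(comp))
              else paste0(a, ".drug_cost"))
    pars <- c(pars, paste0(a, ".", c("second_line_cost", "hospitalization_cost",
                                     "ae_cost", "tests_cost")))
  }
  pars <- c(pars, "u_efs", "u_pd", "discount_rate")
  base <- vapply(pars, get_parameter, numeric(1), config = config)
  low <- base * (1 - rel)
  high <- base * (1 + rel)
  high[pars %in% c("u_efs", "u_pd")] <- pmin(high[pars %in% c("u_efs", "u_pd")], 1)
  low[pars == "discount_rate"] <- 0
  high[pars == "discount_rate"] <- 0.05
  data.frame(parameter = pars, low = low, high = high, row.names = NULL)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the model with each parameter in turn set to the low and high
#' end of its range, all other parameters at base, and ranks parameters
#' by the absolute ICER span they induce (tornado order).
#'
#' @param config A `cea_config`.
#' @param ranges A data.frame with columns `parameter`, `low`, `high`;
#'   defaults to [default_dsa_ranges()]. Each range must bracket the base
#'   value.
#' @param shape Weibull shape for the survival curves (default 1).
#'
#' @return A `dsa_result` data.frame with columns `parameter`,
#'   `base_value`, `low`, `high`, `icer_low`, `icer_high`, `span`,
#'   sorted by decreasing `span`, with attribute `base_icer`.
#' @export
one_way_dsa <- function(config, ranges = default_dsa_ranges(config), shape = 1) {
  stopifnot(inherits(config, "cea_config"),
            all(c("parameter", "low", "high") %in% names(ranges)))
  base_icer <- run_base_case(config, shape = shape)$icer
  n <- nrow(ranges)
  base_value <- icer_low <- icer_high <- numeric(n)
  for (i in seq_len(n)) {
    nm <- ranges$parameter[i]
    b <- get_parameter(config, nm)
    if (!(ranges$low[i] <= b && b <= ranges$high[i]))
      validation_error(sprintf(
        "range [%g, %g] for '%s' does not bracket the base value %g",
        ranges$low[i], ranges$high[i], nm, b))
    base_value[i] <- b
    icer_low[i] <- eval_icer_at(config, setNames(ranges$low[i], nm), shape)$icer
    icer_high[i] <- eval_icer_at(config, setNames(ranges$high[i], nm), shape)$icer
  }
  out <- data.frame(parameter = ranges$parameter, base_value = base_value,
                    low = ranges$low, high = ranges$high,
                    icer_low = icer_low, icer_high = icer_high,
                    span = abs(icer_high - icer_low))
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer, class = c("dsa_result", "data.frame"))
}

#' Threshold value of a parameter for a target ICER
#'
#' Bisection search for the parameter value at which the model ICER
#' equals a target (typically the willingness-to-pay threshold), to a
#' tolerance of $1/QALY. The ICER must be monotone in the parameter over
#' the bounds and bracket the target, otherwise a
#' `mbcea_no_threshold` error signals that no threshold lies in range.
#'
#' @param config A `cea_config`.
#' @param parameter Parameter name.
#' @param target_icer Target ICER in USD/QALY (default the configured
#'   willingness-to-pay threshold).
#' @param bounds Length-2 numeric search interval for the parameter.
#' @param tol Tolerance on |ICER - target| (default $1/QALY).
#' @param max_iter Maximum bisection iterations (default 100).
#' @param shape Weibull shape (default 1).
#'
#' @return The parameter value at which the ICER meets the target.
#' @export
threshold_search <- function(config, parameter, target_icer = config$settings$wtp_threshold,
                             bounds, tol = 1, max_iter = 100, shape = 1) {
  f <- function(x)
    eval_icer_at(config, setNames(x, parameter), shape)$icer - target_icer
  flo <- f(bounds[1])
  fhi <- f(bounds[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    mbcea_error(sprintf("no threshold in range for '%s': ICER does not cross %g on [%g, %g]",
                        parameter, target_icer, bounds[1], bounds[2]),
                "mbcea_no_threshold")
  lo <- bounds[1]; hi <- bounds[2]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (!is.na(fm) && abs(fm) <= tol) return(mid)
    if (is.na(fm) || fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  mbcea_error("bisection did not converge to the requested tolerance",
              "mbcea_no_threshold")
}

#' Moment-matched Gamma parameters
#'
#' Shape/scale of a Gamma distribution with the given mean and standard
#' error: shape = (mean/se)^2, scale = se^2/mean.
#'
#' @param mean,se Target mean and standard error (positive).
#' @return List with `shape` and `scale`.
#' @export
gamma_moment_params <- function(mean, se) {
  if (mean <= 0 || se <= 0)
    validation_error("gamma moment match requires positive mean and se")
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Moment-matched Beta parameters
#'
#' Alpha/beta of a Beta distribution with the given mean and standard
#' error; infeasible when se^2 >= mean(1 - mean).
#'
#' @param mean,se Target mean (in (0,1)) and standard error.
#' @return List with `alpha` and `beta`.
#' @export
beta_moment_params <- function(mean, se) {
  if (mean <= 0 || mean >= 1)
    validation_error("beta moment match requires mean in (0, 1)")
  if (se^2 >= mean * (1 - mean))
    validation_error("beta moment match infeasible: se^2 >= mean(1-mean)")
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

psa_parameter_table <- function(config, cost_se_frac, utility_se_frac,
                                median_se_frac) {
  pars <- character(0); kind <- character(0)
  for (a in c("tib", "ti")) {
    comp <- config$arms[[a]]$drug_cost_components
    cost_pars <- c(if (!is.null(comp)) paste0(a, ".drug.", names(comp))
                   else paste0(a, ".drug_cost"),
                   paste0(a, ".", c("second_line_cost", "hospitalization_cost",
                                    "ae_cost", "tests_cost")))
    pars <- c(pars, cost_pars, paste0(a, ".median_efs"), paste0(a, ".median_os"))
    kind <- c(kind, rep("cost", length(cost_pars)), "median", "median")
  }
  pars <- c(pars, "u_efs", "u_pd")
  kind <- c(kind, "utility", "utility")
  base <- vapply(pars, get_parameter, numeric(1), config = config)
  se <- ifelse(kind == "cost", cost_se_frac,
               ifelse(kind == "median", median_se_frac, utility_se_frac)) * base
  data.frame(parameter = pars, kind = kind, base = base, se = se,
             row.names = NULL)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo analysis drawing every cost parameter from a
#' moment-matched Gamma distribution, the two survival medians per arm
#' from Gammas, and the two state utilities from Betas (redrawn until
#' the progressed-disease utility does not exceed the event-free
#' utility), then re-evaluating the model per iteration. The published
#' analysis gives the distribution families but no dispersion; the
#' default standard errors are 20% of the mean for costs and 10% for
#' utilities and medians, and are explicit arguments.
#'
#' @param config A `cea_config`.
#' @param seed Integer RNG seed; a fixed seed reproduces the draws
#'   bit-for-bit.
#' @param iterations Number of Monte-Carlo iterations (default the
#'   configured `psa_iterations`, 1000).
#' @param cost_se_frac,utility_se_frac,median_se_frac Standard errors as
#'   fractions of the parameter means.
#' @param shape Weibull shape for the survival curves (default 1).
#'
#' @return A `psa_result`: list with `draws` (data.frame of parameter
#'   draws, one row per iteration), `points` (data.frame with
#'   `inc_cost`, `inc_qaly`, `icer`), `ceac` (data.frame `wtp`,
#'   `prob_cost_effective` on a grid from 0 to twice the configured
#'   threshold) and `seed`.
#' @export
run_psa <- function(config, seed = 1L,
                    iterations = config$settings$psa_iterations,
                    cost_se_frac = 0.2, utility_se_frac = 0.1,
                    median_se_frac = 0.1, shape = 1) {
  stopifnot(inherits(config, "cea_config"))
  tab <- psa_parameter_table(config, cost_se_frac, utility_se_frac,
                             median_se_frac)
  # resolve all distributions up front so infeasible assumptions fail fast
  dists <- lapply(seq_len(nrow(tab)), function(i) {
    if (tab$base[i] == 0) return(list(kind = "degenerate"))
    if (tab$kind[i] == "utility")
      c(list(kind = "beta"), beta_moment_params(tab$base[i], tab$se[i]))
    else
      c(list(kind = "gamma"), gamma_moment_params(tab$base[i], tab$se[i]))
  })
  set.seed(as.integer(seed))
  n <- as.integer(iterations)
  draws <- matrix(NA_real_, n, nrow(tab),
                  dimnames = list(NULL, tab$parameter))
  iu_efs <- which(tab$parameter == "u_efs")
  iu_pd <- which(tab$parameter == "u_pd")
  for (j in seq_len(nrow(tab))) {
    d <- dists[[j]]
    draws[, j] <- switch(d$kind,
      degenerate = rep(0, n),
      gamma = rgamma(n, shape = d$shape, scale = d$scale),
      beta = rbeta(n, d$alpha, d$beta))
  }
  # enforce u_pd <= u_efs by joint redraw of the violating iterations
  bad <- which(draws[, iu_pd] > draws[, iu_efs])
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    de <- dists[[iu_efs]]; dp <- dists[[iu_pd]]
    draws[bad, iu_efs] <- rbeta(length(bad), de$alpha, de$beta)
    draws[bad, iu_pd] <- rbeta(length(bad), dp$alpha, dp$beta)
    bad <- which(draws[, iu_pd] > draws[, iu_efs])
    guard <- guard + 1L
  }
  inc_cost <- inc_qaly <- icer <- numeric(n)
  for (i in seq_len(n)) {
    res <- eval_icer_at(config, draws[i, ], shape = shape)
    inc_cost[i] <- res$incremental_cost
    inc_qaly[i] <- res$incremental_qaly
    icer[i] <- if (res$incremental_qaly != 0)
      res$incremental_cost / res$incremental_qaly else NA_real_
  }
  points <- data.frame(inc_cost = inc_cost, inc_qaly = inc_qaly, icer = icer)
  wtp_grid <- seq(0, 2 * config$settings$wtp_threshold, length.out = 101)
  ceac <- data.frame(wtp = wtp_grid,
                     prob_cost_effective = ceac_curve(points, wtp_grid))
  structure(list(draws = as.data.frame(draws), points = points, ceac = ceac,
                 seed = as.integer(seed)),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of Monte-Carlo
#' iterations in which the intervention has positive net monetary
#' benefit, lambda * dQALY - dCost > 0.
#'
#' @param points Data.frame with columns `inc_cost` and `inc_qaly`
#'   (e.g. the `points` element of [run_psa()]).
#' @param wtp_grid Willingness-to-pay values in USD/QALY.
#'
#' @return Numeric vector of probabilities, one per grid value.
#' @export
ceac_curve <- function(points, wtp_grid) {
  if (nrow(points) == 0L) domain_error("empty PSA point set")
  vapply(wtp_grid, function(lambda)
    mean(lambda * points$inc_qaly - points$inc_cost > 0), numeric(1))
}

#' Median ICER of a probabilistic sensitivity analysis
#'
#' Median of the per-iteration ICERs over iterations with positive
#' incremental QALYs (ratios are not comparable across quadrants of the
#' cost-effectiveness plane).
#'
#' @param psa A `psa_result`.
#' @return Median ICER in USD/QALY.
#' @export
psa_median_icer <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  keep <- !is.na(psa$points$icer) & psa$points$inc_qaly > 0
  median(psa$points$icer[keep])
}
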