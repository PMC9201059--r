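#' @importFrom stats integrate median optimize qgamma quantile rbeta rgamma
#'   runif setNames uniroot
#' @importFrom utils modifyList read.csv write.csv
NULL

# Internal helper: classed errors so callers can distinguish validation,
# domain and fit failures from ordinary errors.
mbcea_error <- function(msg, class) {
  stop(structure(
    class = c(class, "mbcea_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) mbcea_error(msg, "mbcea_validation_error")
domain_error <- function(msg) mbcea_error(msg, "mbcea_domain_error")

check_number <- function(x, field) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) || is.na(x))
    validation_error(sprintf("field '%s' must be a single number", field))
  as.numeric(x)
}

#' Economic model settings
#'
#' Global settings of the cost-effectiveness model: discounting,
#' willingness-to-pay, currency conversion and the cycle structure of the
#' Markov cohort simulation (1-month cycles, 10-year horizon, termination
#' once 99% of the cohort is absorbed in the death state).
#'
#' @param annual_discount_rate Annual discount rate applied to both costs
#'   and QALYs, as a fraction per year (default 0.03).
#' @param wtp_threshold Willingness-to-pay threshold in USD per QALY
#'   (default 38136.26, three times China's per-capita GDP).
#' @param exchange_rate CNY per USD (default 6.437).
#' @param cycle_length Cycle length in months; the model is defined on
#'   monthly cycles, so this is fixed at 1.
#' @param horizon_cycles Number of monthly cycles in the time horizon
#'   (default 120, i.e. 10 years).
#' @param termination_fraction The cohort fraction in the death state at
#'   which the simulation terminates early (default 0.99).
#' @param psa_iterations Monte-Carlo iterations for the probabilistic
#'   sensitivity analysis (default 1000).
#'
#' @return An object of class `economic_settings`.
#' @export
economic_settings <- function(annual_discount_rate = 0.03,
                              wtp_threshold = 38136.26,
                              exchange_rate = 6.437,
                              cycle_length = 1,
                              horizon_cycles = 120,
                              termination_fraction = 0.99,
                              psa_iterations = 1000) {
  s <- list(
    annual_discount_rate = check_number(annual_discount_rate, "annual_discount_rate"),
    wtp_threshold = check_number(wtp_threshold, "wtp_threshold"),
    exchange_rate = check_number(exchange_rate, "exchange_rate"),
    cycle_length = check_number(cycle_length, "cycle_length"),
    horizon_cycles = as.integer(check_number(horizon_cycles, "horizon_cycles")),
    termination_fraction = check_number(termination_fraction, "termination_fraction"),
    psa_iterations = as.integer(check_number(psa_iterations, "psa_iterations"))
  )
  if (s$annual_discount_rate < 0 || s$annual_discount_rate >= 1)
    validation_error("invariant violated: 0 <= annual_discount_rate < 1")
  if (s$wtp_threshold <= 0)
    validation_error("invariant violated: wtp_threshold > 0")
  if (s$exchange_rate <= 0)
    validation_error("invariant violated: exchange_rate > 0")
  if (s$cycle_length != 1)
    validation_error("invariant violated: cycle_length is fixed at 1 month")
  if (s$horizon_cycles < 1)
    validation_error("invariant violated: horizon_cycles >= 1")
  if (s$termination_fraction <= 0 || s$termination_fraction > 1)
    validation_error("invariant violated: 0 < termination_fraction <= 1")
  if (s$psa_iterations < 1)
    validation_error("invariant violated: psa_iterations >= 1")
  structure(s, class = "economic_settings")
}

#' Treatment-arm parameters
#'
#' All per-arm quantities of the base-case model: reported median
#' event-free and overall survival, and the per-cycle cost components
#' (drug acquisition, second-line treatment after progression,
#' hospitalization, grade 3-4 adverse-event management, and tests).
#' Costs are in USD per monthly cycle. Active treatment is capped at
#' `max_treatment_cycles` courses (default 12), after which only tests
#' and hospitalization continue to accrue in the event-free state.
#'
#' @param name Arm label, e.g. `"T+I+B"`.
#' @param median_efs Median event-free survival in months.
#' @param median_os Median overall survival in months.
#' @param drug_cost_per_cycle Drug acquisition cost per treatment cycle, USD.
#' @param second_line_cost_per_cycle Second-line treatment cost per cycle in
#'   the progressed-disease state, USD.
#' @param hospitalization_cost_per_cycle Hospitalization cost per cycle, USD.
#' @param ae_cost_per_cycle Grade 3-4 adverse-event management cost per
#'   treatment cycle, USD.
#' @param tests_cost_per_cycle Cost of tests (MRI, biochemistry, ...) per
#'   cycle, USD.
#' @param max_treatment_cycles Maximum number of treatment courses
#'   (default 12).
#' @param drug_cost_components Optional named list decomposing
#'   `drug_cost_per_cycle` into individual drugs (e.g. `tmz`, `irt`, `bev`);
#'   when given, the components must sum to `drug_cost_per_cycle` within
#'   $0.02. Used by the sensitivity analyses to vary single drugs.
#'
#' @return An object of class `arm_parameters`.
#' @export
arm_parameters <- function(name,
                           median_efs, median_os,
                           drug_cost_per_cycle,
                           second_line_cost_per_cycle,
                           hospitalization_cost_per_cycle,
                           ae_cost_per_cycle,
                           tests_cost_per_cycle,
                           max_treatment_cycles = 12,
                           drug_cost_components = NULL) {
  a <- list(
    name = as.character(name),
    median_efs = check_number(median_efs, "median_efs"),
    median_os = check_number(median_os, "median_os"),
    drug_cost_per_cycle = check_number(drug_cost_per_cycle, "drug_cost_per_cycle"),
    second_line_cost_per_cycle = check_number(second_line_cost_per_cycle, "second_line_cost_per_cycle"),
    hospitalization_cost_per_cycle = check_number(hospitalization_cost_per_cycle, "hospitalization_cost_per_cycle"),
    ae_cost_per_cycle = check_number(ae_cost_per_cycle, "ae_cost_per_cycle"),
    tests_cost_per_cycle = check_number(tests_cost_per_cycle, "tests_cost_per_cycle"),
    max_treatment_cycles = as.integer(check_number(max_treatment_cycles, "max_treatment_cycles")),
    drug_cost_components = drug_cost_components
  )
  costs <- c("drug_cost_per_cycle", "second_line_cost_per_cycle",
             "hospitalization_cost_per_cycle", "ae_cost_per_cycle",
             "tests_cost_per_cycle")
  for (f in costs)
    if (a[[f]] < 0) validation_error(sprintf("invariant violated: %s >= 0", f))
  if (!(a$median_efs > 0 && a$median_efs <= a$median_os))
    validation_error("invariant violated: 0 < median_efs <= median_os")
  if (a$max_treatment_cycles < 0)
    validation_error("invariant violated: max_treatment_cycles >= 0")
  if (!is.null(drug_cost_components)) {
    comp <- vapply(drug_cost_components, check_number, numeric(1),
                   field = "drug_cost_components")
    if (any(comp < 0))
      validation_error("invariant violated: drug cost components >= 0")
    if (abs(sum(comp) - a$drug_cost_per_cycle) > 0.02)
      validation_error(sprintf(
        "invariant violated: drug_cost_components sum (%.4f) must equal drug_cost_per_cycle (%.4f) within $0.02",
        sum(comp), a$drug_cost_per_cycle))
    a$drug_cost_components <- as.list(comp)
  }
  structure(a, class = "arm_parameters")
}

#' Health-state utility weights
#'
#' Annual utility weights for the three health states. Per-cycle QALY
#' increments are the annual weight divided by 12.
#'
#' @param u_efs Utility of the event-free survival state (default 0.89).
#' @param u_pd Utility of the progressed-disease state (default 0.73).
#' @param u_death Utility of the death state; fixed at 0.
#'
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_efs = 0.89, u_pd = 0.73, u_death = 0) {
  u <- list(u_efs = check_number(u_efs, "u_efs"),
            u_pd = check_number(u_pd, "u_pd"),
            u_death = check_number(u_death, "u_death"))
  if (!(u$u_death >= 0 && u$u_death <= u$u_pd && u$u_pd <= u$u_efs && u$u_efs <= 1))
    validation_error("invariant violated: 0 <= u_death <= u_pd <= u_efs <= 1")
  if (u$u_death != 0)
    validation_error("invariant violated: u_death is fixed at 0")
  structure(u, class = "utility_set")
}

#' Regimen dosing schedule
#'
#' Dosing of the triplet regimen: temozolomide 50 mg/m2 orally for 5 days,
#' irinotecan 50 mg/m2 intravenously for 5 days, and bevacizumab 10 mg/kg
#' on days 1 and 15 of each 28-day course. The doublet arm uses the same
#' schedule with zero bevacizumab administrations.
#'
#' @param tmz_dose Temozolomide dose, mg/m2/day.
#' @param tmz_days Temozolomide days per cycle.
#' @param irt_dose Irinotecan dose, mg/m2/day.
#' @param irt_days Irinotecan days per cycle.
#' @param bev_dose Bevacizumab dose, mg/kg/administration.
#' @param bev_administrations_per_cycle Bevacizumab administrations per cycle.
#'
#' @return An object of class `regimen_dosing`.
#' @export
regimen_dosing <- function(tmz_dose = 50, tmz_days = 5,
                           irt_dose = 50, irt_days = 5,
                           bev_dose = 10, bev_administrations_per_cycle = 2) {
  d <- list(tmz_dose = check_number(tmz_dose, "tmz_dose"),
            tmz_days = check_number(tmz_days, "tmz_days"),
            irt_dose = check_number(irt_dose, "irt_dose"),
            irt_days = check_number(irt_days, "irt_days"),
            bev_dose = check_number(bev_dose, "bev_dose"),
            bev_administrations_per_cycle =
              check_number(bev_administrations_per_cycle, "bev_administrations_per_cycle"))
  if (any(unlist(d) < 0))
    validation_error("invariant violated: doses and day counts must be >= 0")
  structure(d, class = "regimen_dosing")
}

#' Convert CNY amounts to USD
#'
#' @param amount Amount in CNY (non-negative; vectorized).
#' @param exchange_rate CNY per USD (default 6.437).
#'
#' @return Amount in USD.
#' @export
#'
#' @examples
#' cny_to_usd(6.437) # 1 USD
cny_to_usd <- function(amount, exchange_rate = 6.437) {
  if (!is.numeric(amount) || any(is.na(amount)))
    domain_error("amount must be numeric")
  if (any(amount < 0)) domain_error("amount must be non-negative")
  if (length(exchange_rate) != 1L || !is.numeric(exchange_rate) || exchange_rate <= 0)
    domain_error("exchange_rate must be a single positive number")
  amount / exchange_rate
}

#' Pediatric body surface area
#'
#' Body surface area from body weight via the pediatric linear formula
#' BSA (m2) = 1.05 + (weight - 30) * 0.02.
#'
#' @param weight Body weight in kg (positive; vectorized).
#'
#' @return Body surface area in m2.
#' @export
#'
#' @examples
#' body_surface_area(40) # 1.25 m2
body_surface_area <- function(weight) {
  if (!is.numeric(weight) || any(is.na(weight)))
    domain_error("weight must be numeric")
  if (any(weight <= 0)) domain_error("weight must be positive")
  1.05 + (weight - 30) * 0.02
}

#' Per-cycle drug amounts for a given body weight
#'
#' Milligram amounts per 28-day course: body-surface-area-scaled for
#' temozolomide and irinotecan, weight-scaled for bevacizumab. Exposed for
#' what-if dose calculations; the base-case model takes per-cycle drug
#' costs directly from the listed prices.
#'
#' @param dosing A [regimen_dosing()] object.
#' @param weight Body weight in kg.
#'
#' @return Named numeric vector with elements `tmz_mg`, `irt_mg`, `bev_mg`.
#' @export
doses_per_cycle <- function(dosing, weight = 40) {
  stopifnot(inherits(dosing, "regimen_dosing"))
  bsa <- body_surface_area(weight)
  c(tmz_mg = dosing$tmz_dose * bsa * dosing$tmz_days,
    irt_mg = dosing$irt_dose * bsa * dosing$irt_days,
    bev_mg = dosing$bev_dose * weight * dosing$bev_administrations_per_cycle)
}

# ---- configuration I/O -----------------------------------------------------

arm_fields <- c("name", "median_efs", "median_os", "drug_cost_per_cycle",
                "second_line_cost_per_cycle", "hospitalization_cost_per_cycle",
                "ae_cost_per_cycle", "tests_cost_per_cycle")

build_arm <- function(lst, key) {
  missing <- setdiff(setdiff(arm_fields, "name"), names(lst))
  if (length(missing))
    validation_error(sprintf("arm '%s' is missing required field(s): %s",
                             key, paste(missing, collapse = ", ")))
  arm_parameters(
    name = if (is.null(lst$name)) key else lst$name,
    median_efs = lst$median_efs,
    median_os = lst$median_os,
    drug_cost_per_cycle = lst$drug_cost_per_cycle,
    second_line_cost_per_cycle = lst$second_line_cost_per_cycle,
    hospitalization_cost_per_cycle = lst$hospitalization_cost_per_cycle,
    ae_cost_per_cycle = lst$ae_cost_per_cycle,
    tests_cost_per_cycle = lst$tests_cost_per_cycle,
    max_treatment_cycles = if (is.null(lst$max_treatment_cycles)) 12 else lst$max_treatment_cycles,
    drug_cost_components = lst$drug_cost_components
  )
}

#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration holding the economic settings, the
#' two treatment arms (blocks `tib` and `ti` under `arms`), the utility
#' weights and optionally the dosing schedule. Absent optional fields are
#' filled with the documented defaults; every invariant is checked and a
#' violation raises a validation error naming the field.
#'
#' The configuration bundled with the package
#' (`system.file("extdata", "table1.yaml", package = "mbcea")`) carries the
#' base-case parameter set of the published analysis.
#'
#' @param path Path to a YAML or JSON configuration file.
#'
#' @return An object of class `cea_config`: a list with elements
#'   `settings` ([economic_settings()]), `arms` (named list of
#'   [arm_parameters()] with entries `tib` and `ti`), `utilities`
#'   ([utility_set()]), `dosing` ([regimen_dosing()]) and
#'   `default_weight_kg`.
#' @export
#'
#' @examples
#' cfg <- load_config(system.file("extdata", "table1.yaml", package = "mbcea"))
#' cfg$arms$tib$drug_cost_per_cycle
load_config <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw A nested list with the same structure as the YAML file.
#' @export
config_from_list <- function(raw) {
  if (is.null(raw$arms) || is.null(raw$arms$tib) || is.null(raw$arms$ti))
    validation_error("config must contain arm blocks 'arms$tib' and 'arms$ti'")
  settings <- do.call(economic_settings, as.list(raw$settings))
  utilities <- do.call(utility_set, as.list(raw$utilities))
  dosing <- do.call(regimen_dosing, as.list(raw$dosing))
  structure(list(
    settings = settings,
    arms = list(tib = build_arm(raw$arms$tib, "tib"),
                ti = build_arm(raw$arms$ti, "ti")),
    utilities = utilities,
    dosing = dosing,
    default_weight_kg = if (is.null(raw$default_weight_kg)) 40
                        else check_number(raw$default_weight_kg, "default_weight_kg")
  ), class = "cea_config")
}

#' Serialize a configuration back to YAML
#'
#' Round-trips with [load_config()]: writing a loaded configuration and
#' loading it again yields identical parameters.
#'
#' @param config A `cea_config` object.
#' @param path Output file path (`.yaml` or `.json`).
#'
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  raw <- list(
    settings = unclass(config$settings),
    arms = lapply(config$arms, function(a) {
      a <- unclass(a)
      if (is.null(a$drug_cost_components)) a$drug_cost_components <- NULL
      a
    }),
    utilities = unclass(config$utilities),
    dosing = unclass(config$dosing),
    default_weight_kg = config$default_weight_kg
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("Cost-effectiveness model configuration\n")
  cat(sprintf("  arms: %s vs %s\n", x$arms$tib$name, x$arms$ti$name))
  cat(sprintf("  medians (EFS/OS, months): %g/%g vs %g/%g\n",
              x$arms$tib$median_efs, x$arms$tib$median_os,
              x$arms$ti$median_efs, x$arms$ti$median_os))
  cat(sprintf("  discount %.1f%%/yr, WTP $%.2f/QALY, horizon %d cycles\n",
              100 * x$settings$annual_discount_rate, x$settings$wtp_threshold,
              x$settings$horizon_cycles))
  invisible(x)
}
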