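format_num <- function(x) ifelse(is.na(x), "/", sprintf("%.3f", x))

write_manifest <- function(outdir, subcommand, config_path, seed = NA) {
  manifest <- list(
    config = as.character(config_path),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    subcommand = subcommand,
    output_directory = outdir,
    package_version = as.character(utils::packageVersion("mbcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    mbcea_error(sprintf("cannot create output directory: %s", outdir),
                "mbcea_io_error")
  outdir
}

#' Base-case analysis to files
#'
#' Runs the base-case cost-effectiveness analysis and writes `icer.csv`
#' (one row per arm plus an incremental row, with the per-state cost and
#' QALY breakdown, totals, average C/E and ICER, rounded to 3 decimals)
#' and per-arm traces `trace_tib.csv` / `trace_ti.csv` (cycle, state
#' occupancy, discounted cost and QALY increments). A `run_manifest.json`
#' records how the outputs were produced.
#'
#' @param config_path Path to a configuration file (see [load_config()]).
#' @param outdir Output directory (created if needed).
#' @param shape Weibull shape for the survival curves (default 1).
#'
#' @return Invisibly, the `cea_result` of the run.
#' @export
cmd_base_case <- function(config_path, outdir, shape = 1) {
  config <- load_config(config_path)
  ensure_outdir(outdir)
  bc <- run_base_case(config, shape = shape)
  res <- bc$result
  tib <- res$intervention; ti <- res$comparator
  rows <- data.frame(
    arm = c(tib$name, ti$name, "incremental"),
    cEFS = format_num(c(tib$c_efs, ti$c_efs, NA)),
    cPD = format_num(c(tib$c_pd, ti$c_pd, NA)),
    uEFS = format_num(c(tib$u_efs_total, ti$u_efs_total, NA)),
    uPD = format_num(c(tib$u_pd_total, ti$u_pd_total, NA)),
    total_costs = format_num(c(tib$total_cost, ti$total_cost, res$incremental_cost)),
    total_effectiveness = format_num(c(tib$total_qaly, ti$total_qaly, res$incremental_qaly)),
    ce_ratio = format_num(c(tib$ce_ratio, ti$ce_ratio, NA)),
    icer = c("", "", format_num(res$icer)),
    dominance = c("", "", res$dominance)
  )
  write.csv(rows, file.path(outdir, "icer.csv"), row.names = FALSE)
  for (a in c("tib", "ti")) {
    tr <- bc$traces[[a]]
    arm <- config$arms[[a]]
    disc <- discount_factor(config$settings$annual_discount_rate, tr$cycle)
    tr_out <- data.frame(
      cycle = tr$cycle, efs = tr$efs, pd = tr$pd, dead = tr$dead,
      discounted_cost = (tr$efs * state_cycle_cost(arm, "efs", tr$cycle) +
                           tr$pd * state_cycle_cost(arm, "pd", tr$cycle)) * disc,
      discounted_qaly = (tr$efs * config$utilities$u_efs / 12 +
                           tr$pd * config$utilities$u_pd / 12) * disc
    )
    write.csv(tr_out, file.path(outdir, sprintf("trace_%s.csv", a)),
              row.names = FALSE)
  }
  write_manifest(outdir, "base-case", config_path)
  invisible(res)
}

#' One-way sensitivity analysis to files
#'
#' Writes `tornado.csv`, one row per varied parameter sorted by
#' descending ICER span, with a constant `base_icer` column.
#'
#' @param config_path Path to a configuration file.
#' @param outdir Output directory.
#' @param ranges Optional ranges data.frame (see [one_way_dsa()]).
#' @param shape Weibull shape (default 1).
#'
#' @return Invisibly, the `dsa_result`.
#' @export
cmd_dsa <- function(config_path, outdir, ranges = NULL, shape = 1) {
  config <- load_config(config_path)
  ensure_outdir(outdir)
  if (is.null(ranges)) ranges <- default_dsa_ranges(config)
  dsa <- one_way_dsa(config, ranges, shape = shape)
  out <- as.data.frame(dsa)
  out$base_icer <- attr(dsa, "base_icer")
  write.csv(out, file.path(outdir, "tornado.csv"), row.names = FALSE)
  write_manifest(outdir, "dsa", config_path)
  invisible(dsa)
}

#' Probabilistic sensitivity analysis to files
#'
#' Writes `psa_scatter.csv` (one row per Monte-Carlo iteration:
#' incremental cost, incremental QALY, ICER) and `ceac.csv` (the
#' cost-effectiveness acceptability curve).
#'
#' @param config_path Path to a configuration file.
#' @param outdir Output directory.
#' @param seed Integer RNG seed (default 1).
#' @param iterations Optional override of the configured iteration count.
#' @param shape Weibull shape (default 1).
#'
#' @return Invisibly, the `psa_result`.
#' @export
cmd_psa <- function(config_path, outdir, seed = 1L, iterations = NULL,
                    shape = 1) {
  config <- load_config(config_path)
  ensure_outdir(outdir)
  if (is.null(iterations)) iterations <- config$settings$psa_iterations
  psa <- run_psa(config, seed = seed, iterations = iterations, shape = shape)
  write.csv(psa$points, file.path(outdir, "psa_scatter.csv"), row.names = FALSE)
  write.csv(psa$ceac, file.path(outdir, "ceac.csv"), row.names = FALSE)
  write_manifest(outdir, "psa", config_path, seed = seed)
  invisible(psa)
}

#' Synthetic trial to files
#'
#' Simulates a two-arm trial at the base-case medians and writes the
#' per-patient records plus digitized-curve inputs (time, survival,
#' n_at_risk) per arm and endpoint.
#'
#' @param outdir Output directory.
#' @param n_per_arm Patients per arm (default 50).
#' @param seed Integer RNG seed.
#' @param grid_step Digitization grid in months (default 0.5).
#'
#' @return Invisibly, the simulated records.
#' @export
cmd_simulate <- function(outdir, n_per_arm = 50, seed = 1L, grid_step = 0.5) {
  ensure_outdir(outdir)
  spec <- trial_spec(n_per_arm = n_per_arm, seed = seed)
  rec <- simulate_trial(spec)
  write.csv(rec, file.path(outdir, "trial_records.csv"), row.names = FALSE)
  inputs <- km_inputs_from_trial(rec, grid_step = grid_step)
  for (a in names(inputs)) for (ep in names(inputs[[a]])) {
    ci <- inputs[[a]][[ep]]
    write.csv(data.frame(time = ci$times, survival = ci$survival,
                         n_at_risk = ci$n_at_risk),
              file.path(outdir, sprintf("km_%s_%s.csv", a, ep)),
              row.names = FALSE)
  }
  write_manifest(outdir, "simulate", NA_character_, seed = seed)
  invisible(rec)
}

#' Pseudo-IPD reconstruction from a digitized-curve CSV
#'
#' Reads a CSV with columns `time`, `survival`, `n_at_risk`, reconstructs
#' pseudo individual-patient data, refits the requested parametric family
#' and writes `ipd.csv` plus `fit.csv` (family, scale, shape, median).
#'
#' @param curve_csv Input CSV path.
#' @param outdir Output directory.
#' @param family `"exponential"` or `"weibull"`.
#'
#' @return Invisibly, the fitted [survival_curve()].
#' @export
cmd_reconstruct <- function(curve_csv, outdir, family = "exponential") {
  ensure_outdir(outdir)
  tab <- read.csv(curve_csv)
  ci <- km_curve_input(tab$time, tab$survival, tab$time, tab$n_at_risk)
  ipd <- reconstruct_ipd(ci)
  fit <- fit_parametric(ipd, family)
  write.csv(ipd, file.path(outdir, "ipd.csv"), row.names = FALSE)
  write.csv(data.frame(family = fit$family, scale = fit$scale, shape = fit$shape,
                       median = fit$scale * log(2)^(1 / fit$shape)),
            file.path(outdir, "fit.csv"), row.names = FALSE)
  write_manifest(outdir, "reconstruct", curve_csv)
  invisible(fit)
}
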