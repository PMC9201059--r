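test_that("discounting follows the annual-rate monthly-cycle convention", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0, 57), 1.0)
  expect_equal(discount_factor(0.03, 12), 1 / 1.03)
  expect_equal(discount_factor(0.03, 24), 1 / 1.03^2)
  expect_error(discount_factor(-1, 3), class = "mbcea_domain_error")
})

test_that("state costs implement the 12-course treatment cap", {
  cfg <- base_config()
  tib <- cfg$arms$tib
  # on treatment: drug + tests + hospitalization + AE management
  expect_equal(state_cycle_cost(tib, "efs", 3),
               2803.73 + 185.63 + 43.96 + 10.09)
  # beyond the cap only tests and hospitalization continue
  expect_equal(state_cycle_cost(tib, "efs", 13), 185.63 + 43.96)
  expect_equal(state_cycle_cost(tib, "efs", 12), 185.63 + 43.96)  # boundary
  expect_equal(state_cycle_cost(tib, "pd", 40), 233.11)
  expect_equal(state_cycle_cost(tib, "dead", 0), 0)
  expect_equal(state_cycle_cost(cfg$arms$ti, "efs", 0),
               919.90 + 176.56 + 43.96 + 13.87)
  expect_error(state_cycle_cost(tib, "alive", 0),
               class = "mbcea_domain_error")
})

test_that("accumulation annihilates on zero costs and utilities", {
  arm0 <- arm_parameters("zero", 9, 19, 0, 0, 0, 0, 0)
  u0 <- utility_set(0, 0, 0)
  tr <- run_trace(curve_from_median(9), curve_from_median(19),
                  economic_settings())
  out <- accumulate(tr, arm0, u0, economic_settings())
  expect_equal(out$total_cost, 0)
  expect_equal(out$total_qaly, 0)
})

test_that("a year pinned in the event-free state yields its utility weight", {
  tr <- data.frame(cycle = 0:11, efs = 1, pd = 0, dead = 0)
  out <- accumulate(tr, base_config()$arms$tib, utility_set(0.89, 0.73),
                    economic_settings(annual_discount_rate = 0))
  expect_equal(out$total_qaly, 0.89)
  expect_equal(out$u_pd_total, 0)
})

test_that("accumulate matches an independent cycle-by-cycle oracle", {
  cfg <- base_config()
  for (a in c("tib", "ti")) {
    arm <- cfg$arms[[a]]
    tr <- run_trace(curve_from_median(arm$median_efs),
                    curve_from_median(arm$median_os), cfg$settings)
    out <- accumulate(tr, arm, cfg$utilities, cfg$settings)
    # spreadsheet-style re-accumulation, scalar loop, no shared code path
    cost <- qaly <- 0
    for (i in seq_len(nrow(tr))) {
      k <- tr$cycle[i]
      disc <- (1 + cfg$settings$annual_discount_rate)^(-k / 12)
      efs_cost <- if (k < arm$max_treatment_cycles)
        arm$drug_cost_per_cycle + arm$tests_cost_per_cycle +
          arm$hospitalization_cost_per_cycle + arm$ae_cost_per_cycle
      else arm$tests_cost_per_cycle + arm$hospitalization_cost_per_cycle
      cost <- cost + disc * (tr$efs[i] * efs_cost +
                               tr$pd[i] * arm$second_line_cost_per_cycle)
      qaly <- qaly + disc * (tr$efs[i] * cfg$utilities$u_efs +
                               tr$pd[i] * cfg$utilities$u_pd) / 12
    }
    expect_equal(out$total_cost, cost, tolerance = 1e-12)
    expect_equal(out$total_qaly, qaly, tolerance = 1e-12)
    expect_true(abs(out$total_cost - cost) < 1e-9)
  }
})

test_that("outcomes decompose exactly by state and discounting only shrinks", {
  cfg <- base_config()
  bc <- run_base_case(cfg)
  for (o in list(bc$result$intervention, bc$result$comparator)) {
    expect_identical(o$total_cost, o$c_efs + o$c_pd)
    expect_identical(o$total_qaly, o$u_efs_total + o$u_pd_total)
    expect_true(all(unlist(o[c("c_efs", "c_pd", "u_efs_total", "u_pd_total")]) >= 0))
  }
  cfg0 <- cfg
  cfg0$settings$annual_discount_rate <- 0
  bc0 <- run_base_case(cfg0)
  expect_true(bc$result$intervention$total_cost <= bc0$result$intervention$total_cost)
  expect_true(bc$result$intervention$total_qaly <= bc0$result$intervention$total_qaly)
})

test_that("incremental analysis reproduces the published derived identities", {
  res <- compute_icer(arm_outcome(27603.420, 1.147, name = "T+I+B"),
                      arm_outcome(8786.403, 0.867, name = "T+I"))
  expect_lt(abs(res$incremental_cost - 18817.017), 1e-3)
  expect_lt(abs(res$incremental_qaly - 0.280), 1e-3)
  expect_lt(abs(res$icer - 67203.632), 1e-3)
  expect_lt(abs(res$intervention$ce_ratio - 24065.754), 1e-3)
  expect_lt(abs(res$comparator$ce_ratio - 10134.260), 1e-3)
  expect_equal(res$dominance, "none")
})

test_that("degenerate and dominated comparisons are flagged, not divided", {
  same <- arm_outcome(1000, 0.5)
  res <- compute_icer(same, same)
  expect_equal(res$incremental_cost, 0)
  expect_equal(res$incremental_qaly, 0)
  expect_true(is.na(res$icer))
  expect_equal(res$dominance, "undefined")

  dom <- compute_icer(arm_outcome(900, 0.6), arm_outcome(1000, 0.5))
  expect_equal(dom$dominance, "intervention_dominant")
  expect_true(is.na(dom$icer))

  ded <- compute_icer(arm_outcome(1100, 0.4), arm_outcome(1000, 0.5))
  expect_equal(ded$dominance, "intervention_dominated")
  expect_true(is.na(ded$icer))
})

test_that("raising an intervention cost weakly raises the ICER", {
  cfg <- base_config()
  base <- run_base_case(cfg)$icer
  for (p in c("tib.drug.bev", "tib.second_line_cost", "tib.tests_cost")) {
    up <- run_base_case(set_parameter(cfg, p, get_parameter(cfg, p) * 1.3))$icer
    expect_true(up >= base)
  }
})

test_that("the half-cycle correction reduces accumulated totals here", {
  # occupancy declines, so averaging cycle start and end lowers the sums
  cfg <- base_config()
  tr <- run_trace(curve_from_median(9), curve_from_median(19), cfg$settings)
  plain <- accumulate(tr, cfg$arms$tib, cfg$utilities, cfg$settings)
  half <- accumulate(tr, cfg$arms$tib, cfg$utilities, cfg$settings,
                     half_cycle = TRUE)
  expect_true(half$total_cost < plain$total_cost)
  expect_true(half$total_qaly < plain$total_qaly)
})
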