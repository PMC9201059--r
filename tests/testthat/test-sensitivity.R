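test_that("parameter accessors address every varied quantity", {
  cfg <- base_config()
  expect_equal(get_parameter(cfg, "tib.drug.bev"), 1883.83)
  expect_equal(get_parameter(cfg, "ti.tests_cost"), 176.56)
  expect_equal(get_parameter(cfg, "u_efs"), 0.89)
  expect_equal(get_parameter(cfg, "discount_rate"), 0.03)
  expect_equal(get_parameter(cfg, "tib.efs_state_cost"),
               2803.73 + 185.63 + 43.96 + 10.09)
  cfg2 <- set_parameter(cfg, "tib.drug.bev", 1000)
  expect_equal(get_parameter(cfg2, "tib.drug.bev"), 1000)
  # the arm's total drug cost follows its components
  expect_equal(cfg2$arms$tib$drug_cost_per_cycle, 343.75 + 576.15 + 1000)
  # composite rescaling keeps component proportions
  cfg3 <- set_parameter(cfg, "tib.efs_state_cost",
                        get_parameter(cfg, "tib.efs_state_cost") * 0.5)
  expect_equal(get_parameter(cfg3, "tib.efs_state_cost"),
               get_parameter(cfg, "tib.efs_state_cost") * 0.5)
  expect_equal(cfg3$arms$tib$tests_cost_per_cycle, 185.63 * 0.5)
  expect_error(get_parameter(cfg, "no.such.par"),
               class = "mbcea_validation_error")
})

test_that("one-way analysis reproduces the base ICER at base values", {
  cfg <- base_config()
  base_icer <- run_base_case(cfg)$icer
  ranges <- default_dsa_ranges(cfg)
  degenerate <- data.frame(parameter = ranges$parameter,
                           low = NA_real_, high = NA_real_)
  for (i in seq_len(nrow(degenerate))) {
    b <- get_parameter(cfg, degenerate$parameter[i])
    degenerate$low[i] <- b
    degenerate$high[i] <- b
  }
  dsa <- one_way_dsa(cfg, degenerate)
  expect_true(all(dsa$icer_low == base_icer))
  expect_true(all(dsa$icer_high == base_icer))
  expect_true(all(dsa$span == 0))
})

test_that("the tornado ranks cost drivers and keeps one row per parameter", {
  cfg <- base_config()
  ranges <- default_dsa_ranges(cfg)
  # an inert parameter: the WTP threshold does not enter the ICER
  ranges <- rbind(ranges, data.frame(parameter = "wtp_threshold",
                                     low = 30000, high = 50000))
  dsa <- one_way_dsa(cfg, ranges)
  expect_setequal(dsa$parameter, ranges$parameter)
  expect_equal(anyDuplicated(dsa$parameter), 0L)
  expect_true(all(diff(dsa$span) <= 0))           # sorted descending
  expect_equal(dsa$span[dsa$parameter == "wtp_threshold"], 0)
  expect_equal(dsa$parameter[nrow(dsa)], "wtp_threshold")
  # the composite EFS-state cost of the triplet arm and the bevacizumab
  # price dominate the tornado
  expect_true(all(c("tib.efs_state_cost", "tib.drug.bev") %in%
                    dsa$parameter[1:3]))
  # the ICER rises with the bevacizumab price
  bev <- dsa[dsa$parameter == "tib.drug.bev", ]
  expect_gt(bev$icer_high, bev$icer_low)
  expect_gt(bev$span, 0)
})

test_that("ranges that do not bracket the base value are rejected", {
  cfg <- base_config()
  expect_error(one_way_dsa(cfg, data.frame(parameter = "tib.drug.bev",
                                           low = 2000, high = 2500)),
               class = "mbcea_validation_error")
})

test_that("threshold search meets its tolerance and flags flat functions", {
  cfg <- base_config()
  target <- 30000
  x <- threshold_search(cfg, "tib.drug.bev", target_icer = target,
                        bounds = c(100, 1883.83))
  icer_at <- run_base_case(set_parameter(cfg, "tib.drug.bev", x))$icer
  expect_lte(abs(icer_at - target), 1)
  expect_error(threshold_search(cfg, "wtp_threshold", target_icer = 30000,
                                bounds = c(30000, 50000)),
               class = "mbcea_no_threshold")
})

test_that("the published bevacizumab price cut is a 51.4% reduction", {
  expect_equal(round(100 * (1883.83 - 916.19) / 1883.83, 1), 51.4)
})

test_that("moment matching recovers distribution parameters", {
  g <- gamma_moment_params(100, 20)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 4)
  b <- beta_moment_params(0.73, 0.073)
  nu <- 0.73 * (1 - 0.73) / 0.073^2 - 1
  expect_equal(b$alpha, 0.73 * nu)
  expect_equal(b$beta, (1 - 0.73) * nu)
  expect_equal(b$alpha / (b$alpha + b$beta), 0.73)
  expect_error(beta_moment_params(0.5, 0.6),
               class = "mbcea_validation_error")
})

test_that("the probabilistic analysis is reproducible and well calibrated", {
  cfg <- base_config()
  psa1 <- run_psa(cfg, seed = 7, iterations = 1000)
  psa2 <- run_psa(cfg, seed = 7, iterations = 1000)
  expect_identical(psa1$draws, psa2$draws)
  expect_identical(psa1$points, psa2$points)
  expect_equal(nrow(psa1$points), 1000L)
  # unconstrained draws center on their base values (3 SE of the mean);
  # the ordering-truncated utilities carry a small structural shift and
  # get a sanity band instead
  for (nm in names(psa1$draws)) {
    base <- get_parameter(cfg, nm)
    if (nm %in% c("u_efs", "u_pd")) {
      expect_lt(abs(mean(psa1$draws[[nm]]) - base), 0.03)
    } else {
      se_frac <- if (grepl("median", nm)) 0.1 else 0.2
      expect_lt(abs(mean(psa1$draws[[nm]]) - base),
                3 * se_frac * base / sqrt(1000))
    }
  }
  # the utility ordering is enforced in every draw
  expect_true(all(psa1$draws$u_pd <= psa1$draws$u_efs))
})

test_that("the acceptability curve has the net-benefit limits", {
  cfg <- base_config()
  psa <- run_psa(cfg, seed = 3, iterations = 400)
  pts <- psa$points
  expect_equal(ceac_curve(pts, 0), mean(pts$inc_cost < 0))
  expect_equal(ceac_curve(pts, 1e12), mean(pts$inc_qaly > 0))
  # with uniformly positive incremental QALYs the curve is non-decreasing
  pos <- pts[pts$inc_qaly > 0, ]
  grid <- seq(0, 2e5, length.out = 50)
  expect_true(all(diff(ceac_curve(pos, grid)) >= 0))
  expect_true(all(psa$ceac$prob_cost_effective >= 0 &
                    psa$ceac$prob_cost_effective <= 1))
})
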