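test_that("the product-limit estimator matches hand calculations", {
  # two patients, events at 1 and 2
  km <- km_estimate(pseudo_ipd(c(1, 2), c(1, 1)))
  expect_equal(km_survival_at(km, 1.5), 0.5)
  expect_equal(km_survival_at(km, 2), 0)
  # all censored: no drops
  km <- km_estimate(pseudo_ipd(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km$survival == 1))
  # events at 1, 3 with censorings at 2, 4: 0.75 then 0.75 * (1 - 1/2)
  km <- km_estimate(pseudo_ipd(1:4, c(1, 0, 1, 0)))
  expect_equal(km_survival_at(km, 1), 0.75)
  expect_equal(km_survival_at(km, 3), 0.375)
  expect_error(km_estimate(data.frame(time = numeric(0), event = integer(0))),
               class = "mbcea_domain_error")
})

test_that("the product-limit estimator agrees with survival::survfit", {
  set.seed(41)
  for (i in 1:5) {
    n <- 80
    time <- round(rexp(n, 1 / 10), 2)
    event <- as.integer(runif(n) < 0.7)
    km <- km_estimate(pseudo_ipd(time, event))
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    grid <- sort(unique(time))
    expect_equal(km_survival_at(km, grid),
                 summary(sf, times = grid)$surv, tolerance = 1e-12)
  }
})

test_that("reconstruction round-trips a small cohort's interval counts", {
  spec <- trial_spec(n_per_arm = 20, efs_median = 9, os_median = 19,
                     admin_censor_time = 24, seed = 5, arm_names = "a")
  rec <- simulate_trial(spec)
  ki <- km_inputs_from_trial(rec, grid_step = 1)
  ipd <- reconstruct_ipd(ki$efs)
  expect_equal(nrow(ipd), 20L)
  grid <- ki$efs$times
  # interval event counts match the source data exactly
  brk <- c(grid, Inf)
  orig_ev <- rec$efs_time[rec$efs_event == 1]
  rec_ev <- ipd$time[ipd$event == 1]
  expect_equal(as.vector(table(cut(rec_ev, brk))),
               as.vector(table(cut(orig_ev, brk))))
  # and the curve is reproduced on the grid
  km <- km_estimate(ipd)
  expect_true(max(abs(km_survival_at(km, grid) - ki$efs$survival)) <= 0.02)
})

test_that("a flat curve with declining risk numbers yields only censorings", {
  ci <- km_curve_input(times = 0:10, survival = rep(1, 11),
                       risk_times = 0:10, n_at_risk = 20:10)
  ipd <- reconstruct_ipd(ci)
  expect_equal(nrow(ipd), 20L)
  expect_true(all(ipd$event == 0))
})

test_that("invalid digitized inputs are rejected", {
  expect_error(km_curve_input(0:2, c(1, 0.8, 0.9), 0:2, c(10, 8, 9)),
               class = "mbcea_validation_error")   # survival rises
  expect_error(km_curve_input(0:2, c(1, 0.8, 0.7), 0:2, c(10, 8, 9)),
               class = "mbcea_validation_error")   # n_at_risk rises
  expect_error(km_curve_input(0:1, c(1, 1.2), 0:1, c(5, 5)),
               class = "mbcea_validation_error")   # survival above 1
})

test_that("reconstruction is deterministic and accurate at trial scale", {
  spec <- trial_spec(n_per_arm = 2000, efs_median = 9, os_median = 19,
                     admin_censor_time = 24, seed = 1, arm_names = "a")
  rec <- simulate_trial(spec)
  ki <- km_inputs_from_trial(rec, grid_step = 0.5)
  ipd1 <- reconstruct_ipd(ki$efs)
  ipd2 <- reconstruct_ipd(ki$efs)
  expect_identical(ipd1, ipd2)
  fit <- fit_parametric(ipd1, "exponential")
  med <- fit$scale * log(2)
  expect_lt(abs(med - 9) / 9, 0.05)
  # round-trip tolerance on the input grid
  km <- km_estimate(ipd1)
  expect_true(max(abs(km_survival_at(km, ki$efs$times) - ki$efs$survival)) <= 0.02)
})

test_that("round-trip holds across random cohorts of 50+ patients", {
  for (s in 1:5) {
    spec <- trial_spec(n_per_arm = 60, efs_median = 8, os_median = 15,
                       admin_censor_time = 20, seed = s, arm_names = "a")
    rec <- simulate_trial(spec)
    ki <- km_inputs_from_trial(rec, grid_step = 1)
    km <- km_estimate(reconstruct_ipd(ki$efs))
    expect_true(max(abs(km_survival_at(km, ki$efs$times) - ki$efs$survival)) <= 0.02)
  }
})

test_that("parametric fits recover closed forms and simulated truth", {
  # three events at 2, 3, 4 without censoring: rate = 3/9
  fit <- fit_parametric(pseudo_ipd(c(2, 3, 4), c(1, 1, 1)), "exponential")
  expect_equal(1 / fit$scale, 1 / 3)
  # the exponential MLE is events/exposure for arbitrary censored data
  set.seed(43)
  time <- rexp(200, 0.1); event <- as.integer(runif(200) < 0.6)
  fit <- fit_parametric(pseudo_ipd(time, event), "exponential")
  expect_equal(1 / fit$scale, sum(event) / sum(time))
  # no events cannot be fit
  expect_error(fit_parametric(pseudo_ipd(c(1, 2), c(0, 0)), "exponential"),
               class = "mbcea_fit_error")
})

test_that("large-sample fits recover the generating parameters", {
  spec <- trial_spec(n_per_arm = 5000, efs_median = 9, os_median = 19,
                     admin_censor_time = 36, seed = 2, arm_names = "a")
  rec <- simulate_trial(spec)
  ipd <- pseudo_ipd(rec$efs_time, rec$efs_event)
  fe <- fit_parametric(ipd, "exponential")
  expect_lt(abs(fe$scale * log(2) - 9) / 9, 0.05)
  fw <- fit_parametric(ipd, "weibull")
  expect_gt(fw$shape, 0.9)
  expect_lt(fw$shape, 1.1)
})

test_that("the Weibull likelihood fit agrees with survival::survreg", {
  set.seed(44)
  time <- rweibull(400, shape = 1.4, scale = 12)
  cens <- runif(400, 0, 30)
  obs <- pmin(time, cens); event <- as.integer(time <= cens)
  fit <- fit_parametric(pseudo_ipd(obs, event), "weibull")
  sr <- survival::survreg(survival::Surv(obs, event) ~ 1, dist = "weibull")
  expect_equal(fit$shape, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(fit$scale, unname(exp(coef(sr))), tolerance = 1e-3)
})
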