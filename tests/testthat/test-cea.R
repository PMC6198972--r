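test_that("incremental statistics follow the printed-table arithmetic", {
  # recomputing the ICER from published row values: 577 / 0.040
  a <- fake_result(31388, 0.780, "test")
  b <- fake_result(30811, 0.740, "control")
  ic <- icer(a, b)
  expect_equal(ic$delta_cost, 577)
  expect_equal(ic$delta_effect, 0.040, tolerance = 1e-12)
  expect_equal(ic$icer, 577 / 0.040, tolerance = 1e-9)
  expect_equal(round(ic$icer), 14425)

  # dominance bookkeeping
  expect_equal(icer(fake_result(100, 2), fake_result(200, 1))$dominance,
               "dominant")
  expect_equal(icer(fake_result(200, 1), fake_result(100, 2))$dominance,
               "dominated")
  same <- icer(fake_result(100, 1), fake_result(100, 1))
  expect_equal(same$dominance, "no difference")
  expect_true(is.na(same$icer))
  # equal effect, different cost: undefined ratio, cost difference only
  eq <- icer(fake_result(150, 1), fake_result(100, 1))
  expect_true(is.na(eq$icer))
  expect_equal(eq$delta_cost, 50)
})

test_that("net monetary benefit is linear and consistent with the ICER rule", {
  expect_equal(nmb(fake_result(0, 1), 32000), 32000)
  expect_equal(nmb(fake_result(30811, 0.740), 32000), -7131, tolerance = 1e-9)
  expect_error(nmb(fake_result(0, 1), -5), ">= 0")
  # sign of the NMB difference encodes ICER vs WTP whenever dQALY > 0
  set.seed(31)
  for (i in 1:30) {
    a <- fake_result(runif(1, 1e3, 5e4), runif(1, 0.5, 1.5))
    b <- fake_result(runif(1, 1e3, 5e4), a$qalys - runif(1, 0.01, 0.4))
    ic <- icer(a, b)
    for (w in c(0, 1e4, 32000, 1e5)) {
      expect_equal(nmb(a, w) - nmb(b, w) > 0, ic$icer < w,
                   info = sprintf("i=%d w=%g", i, w))
    }
  }
})

test_that("a zero-prevalence test strategy equals control plus test cost", {
  b <- fast_bundle()
  b$run$test_cost_policy <- "all"
  b <- param_set(b, "alk_prevalence", 0)
  ctrl <- evaluate_strategy(strategy_spec("none"), b)
  ngs <- evaluate_strategy(strategy_spec("ngs"), b)
  expect_equal(ngs$cost, ctrl$cost + 1014.49, tolerance = 1e-9)
  expect_equal(ngs$qalys, ctrl$qalys, tolerance = 1e-12)
  expect_equal(ngs$pf_ly, ctrl$pf_ly, tolerance = 1e-12)
  # under the positives allocation the test cost vanishes with prevalence
  b$run$test_cost_policy <- "positives"
  ngs0 <- evaluate_strategy(strategy_spec("ngs"), b)
  expect_equal(ngs0$cost, ctrl$cost, tolerance = 1e-9)
})

test_that("strategy cost is linear in the up-front test cost", {
  b <- fast_bundle()
  b$run$test_cost_policy <- "all"
  base <- evaluate_strategy(strategy_spec("ngs"), b)
  b2 <- param_set(b, "cost_test_ngs", 1514.49)
  shifted <- evaluate_strategy(strategy_spec("ngs"), b2)
  expect_equal(shifted$cost - base$cost, 500, tolerance = 1e-9)
  expect_equal(shifted$qalys, base$qalys, tolerance = 1e-12)
})

test_that("strategy evaluation is a mixture-linear weighted sum", {
  b <- fast_bundle()
  b$run$test_cost_policy <- "all"
  b <- param_set(param_set(b, "ngs_sensitivity", 0.9),
                 "ngs_specificity", 0.9)
  ngs <- evaluate_strategy(strategy_spec("ngs"), b)
  ex <- expand_strategy(strategy_spec("ngs"),
                        param_base(b, "alk_prevalence"), b)
  total <- 0
  for (i in seq_len(nrow(ex$subcohorts))) {
    role <- ex$subcohorts$pfs_curve_role[i]
    cv <- switch(role,
                 crizotinib = weibull_curve(0.0211, 1.5326,
                                            b$run$criz_time_unit),
                 chemo = weibull_curve(0.0663, 0.8604, b$run$chemo_time_unit),
                 supportive = supportive_pfs_curve(
                   weibull_curve(0.0663, 0.8604, b$run$chemo_time_unit),
                   0.77))
    acc <- accrue(run_trace(cv, b),
                  ifelse(ex$subcohorts$treatment[i] == "crizotinib",
                         "crizotinib", "chemo"), b)
    total <- total + ex$subcohorts$weight[i] * acc$qalys
  }
  expect_equal(ngs$qalys, total, tolerance = 1e-12)
})

test_that("removing the assistance program raises cost but never health", {
  b <- fast_bundle(pap = TRUE)
  with_pap <- evaluate_strategy(strategy_spec("ngs"), b)
  bn <- fast_bundle(pap = FALSE)
  without <- evaluate_strategy(strategy_spec("ngs"), bn)
  expect_gte(without$cost, with_pap$cost)
  expect_equal(without$qalys, with_pap$qalys, tolerance = 1e-12)
  expect_equal(without$pf_ly, with_pap$pf_ly, tolerance = 1e-12)
  # control is untouched by PAP
  expect_equal(evaluate_strategy(strategy_spec("none"), b)$cost,
               evaluate_strategy(strategy_spec("none"), bn)$cost,
               tolerance = 1e-12)
})

test_that("run_cea assembles strategies with incrementals vs control", {
  res <- run_cea(fast_bundle())
  tab <- summary(res)
  expect_equal(tab$strategy, c("control", "NGS panel", "multiplex PCR"))
  expect_true(is.na(tab$icer_vs_control[1]))
  expect_true(all(is.finite(tab$icer_vs_control[-1])))
  expect_true(all(tab$pf_ly <= tab$overall_ly))
  # deterministic: identical rerun
  res2 <- run_cea(fast_bundle())
  expect_equal(summary(res2), tab)
})

test_that("calibration recovers a known generating convention", {
  b <- fast_bundle(horizon_years = 5)
  truth <- list(cycle_days = 28, chemo_time_unit = "week",
                criz_time_unit = "month", salvage_max_cycles = 8,
                pap_paid_days = 56)
  bt <- b
  bt$run$cycle_days <- truth$cycle_days
  bt$run$chemo_time_unit <- truth$chemo_time_unit
  bt$run$criz_time_unit <- truth$criz_time_unit
  bt$run$salvage_max_cycles <- truth$salvage_max_cycles
  bt$run$pap$paid_days <- truth$pap_paid_days
  # synthetic "published" targets generated by the true convention
  ctrl <- evaluate_strategy(strategy_spec("none"), bt)
  targets <- c(control_cost = ctrl$cost, control_pf_ly = ctrl$pf_ly,
               control_ly = ctrl$overall_ly, control_qalys = ctrl$qalys)
  grid <- expand.grid(cycle_days = c(21, 28), chemo_time_unit = c("week", "month"),
                      salvage_max_cycles = c(4, 8),
                      stringsAsFactors = FALSE)
  cal <- calibrate_conventions(bt, grid, targets)
  expect_equal(cal$best$cycle_days, 28)
  expect_equal(cal$best$chemo_time_unit, "week")
  expect_equal(cal$best$salvage_max_cycles, 8)
  expect_lt(cal$best$max_rel_err, 1e-12)

  # a single-candidate grid is returned unconditionally
  one <- calibrate_conventions(bt, data.frame(cycle_days = 30), targets)
  expect_equal(one$best$cycle_days, 30)
  expect_error(calibrate_conventions(bt, data.frame()), "non-empty")
})
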