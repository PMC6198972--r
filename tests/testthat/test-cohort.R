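test_that("discount factors have their closed form", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(1, 0.05), 0.9524, tolerance = 5e-5)
  expect_equal(discount_factor(10, 0.05), 0.6139, tolerance = 5e-5)
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("trace geometry follows the horizon and cycle length", {
  b <- default_parameters()
  b$run$cycle_days <- 21
  tr <- run_trace(chemo_curve(), b)
  expect_equal(nrow(tr), floor(10 * 365.25 / 21) + 1)
  expect_equal(tr$cycle, 0:(nrow(tr) - 1))
  expect_equal(tr$time_years, tr$cycle * 21 / 365.25)
  expect_equal(tr$discount, (1.05)^(-tr$time_years))
  expect_equal(unlist(tr[1, c("pfs", "progressed", "dead")]),
               c(pfs = 1, progressed = 0, dead = 0))
})

test_that("degenerate chains behave exactly", {
  b <- default_parameters()
  # no progression, no death: the cohort never moves
  b0 <- param_set(b, "p_death_progressed", 0)
  tr0 <- run_trace(weibull_curve(1e-300, 1, "month"), b0)
  expect_true(all(tr0$pfs == 1))
  expect_true(all(tr0$dead == 0))

  # constant 0.5 / 0.5 chain: hand-enumerated two-step occupancy.
  # Progression is memoryless with p = 0.5 when scale = ln 2 in cycle units;
  # the newly progressed face the same-cycle death draw.
  bh <- param_set(b, "p_death_progressed", 0.5)
  bh$run$criz_time_unit <- "cycle"
  trh <- run_trace(weibull_curve(log(2), 1, "cycle"), bh)
  expect_equal(unlist(trh[3, c("pfs", "progressed", "dead")]),
               c(pfs = 0.25, progressed = 0.375, dead = 0.375),
               tolerance = 1e-12)
})

test_that("occupancy is conserved and monotone on arbitrary valid inputs", {
  set.seed(5)
  for (i in 1:15) {
    b <- generate_parameter_bundle(seed = i)
    b$run$horizon_years <- 4
    cv <- weibull_curve(runif(1, 0.005, 0.4), runif(1, 0.4, 2.2),
                        sample(c("month", "week", "cycle"), 1))
    tr <- run_trace(cv, b)
    occ <- tr$pfs + tr$progressed + tr$dead
    expect_true(all(abs(occ - 1) < 1e-9))
    expect_true(all(tr$pfs >= 0 & tr$progressed >= -1e-15 & tr$dead >= 0))
    expect_true(all(diff(tr$dead) >= 0))
    expect_true(all(diff(tr$pfs) <= 0))
    # the progression-free column reproduces the curve itself
    dt <- switch(cv$time_unit, month = b$run$cycle_days / b$run$days_per_month,
                 week = b$run$cycle_days / 7, cycle = 1)
    expect_equal(tr$pfs, weibull_survival(cv, tr$cycle * dt),
                 tolerance = 1e-12)
  }
})

test_that("life-year accrual matches an independent summation oracle", {
  set.seed(21)
  for (i in 1:8) {
    b <- generate_parameter_bundle(seed = 100 + i)
    b$run$horizon_years <- 4
    tr <- run_trace(chemo_curve(), b)
    acc <- accrue(tr, "chemo", b)
    # plain-loop oracle over start-of-cycle occupancy
    n <- nrow(tr) - 1
    cyc_years <- b$run$cycle_days / 365.25
    pf <- ly <- pf_u <- ly_u <- 0
    for (k in seq_len(n)) {
      df <- tr$discount[k]
      pf <- pf + df * tr$pfs[k] * cyc_years
      ly <- ly + df * (tr$pfs[k] + tr$progressed[k]) * cyc_years
      pf_u <- pf_u + tr$pfs[k] * cyc_years
      ly_u <- ly_u + (tr$pfs[k] + tr$progressed[k]) * cyc_years
    }
    expect_equal(acc$pf_ly, pf, tolerance = 1e-12)
    expect_equal(acc$overall_ly, ly, tolerance = 1e-12)
    expect_equal(acc$pf_ly_undisc, pf_u, tolerance = 1e-12)
    expect_equal(acc$overall_ly_undisc, ly_u, tolerance = 1e-12)
    # additivity and ordering
    expect_lte(acc$pf_ly, acc$overall_ly)
    expect_lte(acc$cost, acc$cost_undisc)
    expect_lte(acc$qalys, acc$qalys_undisc)
  }
})

test_that("utility weighting reduces to time in state in the identity case", {
  b <- default_parameters()
  b <- param_set(param_set(b, "u_pfs", 1), "u_progressed", 0)
  b <- param_set(b, "annual_discount", 0)
  tr <- run_trace(chemo_curve(), b)
  acc <- accrue(tr, "chemo", b)
  expect_equal(acc$qalys, acc$pf_ly, tolerance = 1e-12)
})

test_that("crizotinib drug cost follows the closed-form discounted sum", {
  b <- default_parameters(pap = FALSE)
  # keep everyone progression-free: only drug + follow-up accrue
  b0 <- param_set(b, "p_death_progressed", 0)
  tr <- run_trace(weibull_curve(1e-300, 1, "month"), b0)
  acc <- accrue(tr, "crizotinib", b0)
  n <- nrow(tr) - 1
  cyc_years <- b0$run$cycle_days / 365.25
  per_cycle <- 238.1 * b0$run$cycle_days + 55.6
  expected <- sum(per_cycle * (1.05)^(-(0:(n - 1)) * cyc_years))
  expect_equal(acc$cost, expected, tolerance = 1e-9)

  # PAP truncates the bill at paid_days of drug
  bp <- b0; bp$run$pap$enabled <- TRUE
  accp <- accrue(run_trace(weibull_curve(1e-300, 1, "month"), bp),
                 "crizotinib", bp)
  paid_cycles <- bp$run$pap$paid_days / bp$run$cycle_days
  drug_paid <- 238.1 * bp$run$cycle_days *
    sum((1.05)^(-(0:(ceiling(paid_cycles) - 1)) * cyc_years) *
          pmin(1, paid_cycles - 0:(ceiling(paid_cycles) - 1)))
  fu <- 55.6 * sum((1.05)^(-(0:(n - 1)) * cyc_years))
  expect_equal(accp$cost, drug_paid + fu, tolerance = 1e-9)
})

test_that("chemotherapy costs bill whole pemetrexed vials for four cycles", {
  b <- default_parameters()
  b <- param_set(param_set(b, "annual_discount", 0),
                 "p_death_progressed", 0)
  tr <- run_trace(weibull_curve(1e-300, 1, "month"), b)
  acc <- accrue(tr, "chemo", b)
  n <- nrow(tr) - 1
  # 500 mg/m2 x 1.72 m2 = 860 mg -> 2 vials
  per_chemo_cycle <- 2 * 2083.97 + 518.4 + 507.4
  expect_equal(acc$cost, 4 * per_chemo_cycle + n * 55.6, tolerance = 1e-9)
  # proportional billing option
  b$run$pemetrexed_billing <- "proportional"
  acc2 <- accrue(run_trace(weibull_curve(1e-300, 1, "month"), b), "chemo", b)
  expect_equal(acc2$cost, 4 * (1.72 * 2083.97 + 518.4 + 507.4) + n * 55.6,
               tolerance = 1e-9)
})

test_that("switching the discount off never decreases any accrual", {
  b <- fast_bundle()
  tr <- run_trace(chemo_curve(), b)
  acc <- accrue(tr, "chemo", b)
  b0 <- param_set(b, "annual_discount", 0)
  acc0 <- accrue(run_trace(chemo_curve(), b0), "chemo", b0)
  for (f in c("cost", "qalys", "pf_ly", "overall_ly"))
    expect_gte(acc0[[f]], acc[[f]])
})

test_that("the cohort trace round trips through CSV", {
  b <- fast_bundle()
  tr <- run_trace(criz_curve(), b)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(names(back), names(as.data.frame(tr)))
  for (col in names(back))
    expect_identical(back[[col]], as.numeric(tr[[col]]), info = col)
})
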