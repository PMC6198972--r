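test_that("Weibull survival evaluates the actuarial form", {
  crz <- criz_curve()
  expect_equal(weibull_survival(crz, 0), 1)
  expect_equal(weibull_survival(chemo_curve(), 0), 1)
  # frozen closed-form values, independently computed
  expect_equal(weibull_survival(crz, 10), 0.487, tolerance = 5e-4)
  expect_equal(weibull_survival(weibull_curve(0.0663, 1), 10),
               exp(-0.663), tolerance = 1e-12)
  expect_error(weibull_survival(crz, -1), ">= 0")
  expect_error(weibull_curve(-0.1, 1), "scale")
  expect_error(weibull_curve(0.1, 0), "shape")
})

test_that("survival curves are monotone non-increasing", {
  set.seed(42)
  for (i in 1:25) {
    cv <- weibull_curve(runif(1, 0.001, 0.5), runif(1, 0.3, 3))
    s <- weibull_survival(cv, seq(0, 40, by = 0.5))
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("per-cycle transition probabilities follow the hazard shape", {
  # memoryless exponential: constant in t
  expc <- weibull_curve(0.3, 1)
  p <- per_cycle_transition_prob(expc, 0:10)
  expect_equal(p, rep(1 - exp(-0.3), 11))
  # first-cycle value for the crizotinib curve
  expect_equal(per_cycle_transition_prob(criz_curve(), 0),
               1 - exp(-0.0211), tolerance = 1e-4)
  # shape < 1: decreasing hazard, brute-force grid check
  pdec <- per_cycle_transition_prob(weibull_curve(0.0663, 0.8604), 0:20)
  expect_true(all(diff(pdec) < 0))
  # shape > 1: increasing
  pinc <- per_cycle_transition_prob(criz_curve(), 0:20)
  expect_true(all(diff(pinc) > 0))
  expect_true(all(c(p, pdec, pinc) >= 0 & c(p, pdec, pinc) < 1))
  expect_error(per_cycle_transition_prob(expc, -1), ">= 0")
})

test_that("per-cycle probabilities telescope back to the survival curve", {
  set.seed(7)
  for (i in 1:20) {
    cv <- weibull_curve(runif(1, 0.005, 0.3), runif(1, 0.4, 2.5))
    dt <- runif(1, 0.2, 2)
    p <- per_cycle_transition_prob(cv, 0:29, cycle_length = dt)
    expect_equal(prod(1 - p), weibull_survival(cv, 30 * dt),
                 tolerance = 1e-12)
  }
})

test_that("hazard-ratio transform is a proportional-hazards power", {
  expect_equal(apply_hazard_ratio(0.5, 1), 0.5)
  expect_equal(apply_hazard_ratio(0.5, 0.77), 0.5864, tolerance = 5e-5)
  # supportive-care direction used for false positives
  expect_equal(apply_hazard_ratio(0.5, 1 / 0.77), 0.4065, tolerance = 2e-4)
  # composition: hr a then b equals hr a*b
  set.seed(11)
  for (i in 1:20) {
    s <- runif(1, 0.05, 0.99); a <- runif(1, 0.2, 2); bb <- runif(1, 0.2, 2)
    expect_equal(apply_hazard_ratio(apply_hazard_ratio(s, a), bb),
                 apply_hazard_ratio(s, a * bb), tolerance = 1e-12)
  }
  expect_error(apply_hazard_ratio(0.5, 0), "> 0")
  expect_error(apply_hazard_ratio(1.2, 1), "\\(0, 1\\]")
})

test_that("median survival has its closed form", {
  expect_equal(median_survival(weibull_curve(log(2), 1)), 1)
  expect_equal(median_survival(criz_curve()), 9.76, tolerance = 5e-3)
  expect_equal(median_survival(weibull_curve(0.0663, 0.8604)), 15.3,
               tolerance = 5e-3)
})

test_that("scale recalibration hits a target median exactly", {
  cv <- criz_curve()
  r <- recalibrate_scale(cv, median_survival(cv))
  expect_equal(r$scale, cv$scale, tolerance = 1e-12)
  expect_equal(recalibrate_scale(cv, 1)$scale, log(2))
  r2 <- recalibrate_scale(weibull_curve(0.0663, 0.8604), 7.0)
  expect_equal(median_survival(r2), 7.0, tolerance = 1e-12)
  expect_equal(r2$shape, 0.8604)
  expect_error(recalibrate_scale(cv, 0), "> 0")
})

test_that("per-cycle death probability from a median matches the table", {
  expect_equal(round(cycle_prob_from_median(5.4, 21, 30), 3), 0.086)
  # one median per cycle gives exactly one half
  expect_equal(cycle_prob_from_median(5.4, 5.4 * 30, 30), 0.5)
  expect_equal(round(cycle_prob_from_median(5.4, 30, 30), 4), 0.1205)
  expect_error(cycle_prob_from_median(-1, 21, 30), "> 0")
})

test_that("noise-free Kaplan-Meier points are recovered exactly", {
  pts <- generate_km_points(criz_curve(), 1:30, noise_sd = 0)
  fit <- fit_weibull(pts)
  expect_equal(fit$scale, 0.0211, tolerance = 1e-7)
  expect_equal(fit$shape, 1.5326, tolerance = 1e-7)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-10)
  expect_s3_class(fit, "weibull_curve")
  expect_equal(unname(coef(fit)), c(0.0211, 1.5326), tolerance = 1e-7)
  expect_length(residuals(fit), 30)
})

test_that("noisy points are recovered within tolerance", {
  pts <- generate_km_points(criz_curve(), 1:30, noise_sd = 0.01, seed = 101)
  fit <- fit_weibull(pts)
  expect_lt(abs(fit$scale / 0.0211 - 1), 0.05)
  expect_lt(abs(fit$shape / 1.5326 - 1), 0.05)
  expect_gt(fit$fit_r2, 0.97)
})

test_that("degenerate fits are rejected with informative errors", {
  expect_error(fit_weibull(data.frame(time = 1:2, survival = c(0.9, 0.8))),
               "at least 3")
  bad <- data.frame(time = 1:4, survival = c(1, 0.8, 0.5, 0.2))
  expect_error(fit_weibull(bad), "offending times: 1")
  expect_error(fit_weibull(data.frame(time = c(1, 1, 2),
                                      survival = c(0.9, 0.8, 0.7))),
               "strictly increasing")
  expect_error(fit_weibull(data.frame(time = 1:3,
                                      survival = c(0.5, 0.6, 0.4))),
               "non-increasing")
})

test_that("Kaplan-Meier CSV round trips", {
  pts <- generate_km_points(chemo_curve(), c(2, 4, 8, 16), noise_sd = 0.02,
                            seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_km_points(pts, f)
  back <- read_km_points(f)
  expect_equal(back$time, pts$time)
  expect_equal(back$survival, pts$survival, tolerance = 1e-12)
})
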