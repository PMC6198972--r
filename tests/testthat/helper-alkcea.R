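# shared fixtures, all generated in code

criz_curve <- function() weibull_curve(0.0211, 1.5326, "month")
chemo_curve <- function() weibull_curve(0.0663, 0.8604, "month")

# bundle with a short horizon for fast property loops
fast_bundle <- function(horizon_years = 3, ...) {
  b <- default_parameters(...)
  b$run$horizon_years <- horizon_years
  b
}

# a minimal strategy_result for incremental arithmetic tests
fake_result <- function(cost, qalys, name = "x") {
  structure(list(name = name, test = "none", pap = FALSE,
                 cost = cost, qalys = qalys),
            class = "strategy_result")
}

# pin every sampled parameter to its base value (degenerate PSA)
degenerate_bundle <- function(bundle = default_parameters()) {
  for (nm in names(bundle$params)) {
    bundle$params[[nm]]$low <- bundle$params[[nm]]$base
    bundle$params[[nm]]$high <- bundle$params[[nm]]$base
  }
  bundle
}

# proportion of draws in which a test strategy beats control on NMB at the
# bundle's willingness-to-pay (computed from the raw samples)
ce_prob_for_test <- function(psa, strategy, wtp = psa$wtp) {
  s <- psa$samples
  a <- s[s$strategy == strategy, ]
  b <- s[s$strategy == psa$strategies[1L], ]
  mean((a$qalys * wtp - a$cost) > (b$qalys * wtp - b$cost))
}

expect_bundle_equal <- function(a, b) {
  expect_equal(a$params, b$params)
  expect_equal(a$run, b$run)
}
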