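#' Single model parameter with range and PSA distribution
#'
#' A parameter specification carries the base-case value, the deterministic
#' sensitivity range, and the distribution family used in probabilistic
#' sensitivity analysis: `"triangular"` (mode = base, bounds = range, used
#' for costs), `"beta"` (method-of-moments from mean = base and
#' sd = (high - low)/4, used for probabilities, proportions and utilities)
#' or `"fixed"` (never sampled).
#'
#' @param name Identifier.
#' @param base Base-case value.
#' @param low,high Deterministic range; defaults collapse to `base`.
#' @param distribution `"triangular"`, `"beta"` or `"fixed"`.
#' @param units Free-text units, for reporting only.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, base, low = base, high = base,
                           distribution = c("fixed", "triangular", "beta"),
                           units = "") {
  distribution <- match.arg(distribution)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(base), is.numeric(low), is.numeric(high))
  if (low > base || base > high)
    stop(sprintf("parameter '%s': need low <= base <= high, got %g / %g / %g",
                 name, low, base, high), call. = FALSE)
  if (distribution == "beta" && (low < 0 || high > 1))
    stop(sprintf("parameter '%s': beta distribution needs range within [0, 1]",
                 name), call. = FALSE)
  structure(list(name = name, base = base, low = low, high = high,
                 distribution = distribution, units = units),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("%-28s %10g  [%g, %g]  %-10s %s\n", x$name, x$base, x$low,
              x$high, x$distribution, x$units))
  invisible(x)
}

#' Body surface area by the Mosteller formula
#'
#' \eqn{\sqrt{weight \times height / 3600}}; the model's reference patient
#' (65 kg, 164 cm) gives 1.72 m2, which sizes the pemetrexed dose.
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_cm Height in centimetres (> 0).
#' @return Body surface area in m2 (unrounded).
#' @examples
#' bsa_mosteller(65, 164)
#' @export
bsa_mosteller <- function(weight_kg, height_cm) {
  stopifnot(is.numeric(weight_kg), is.numeric(height_cm))
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be > 0", call. = FALSE)
  sqrt(weight_kg * height_cm / 3600)
}

# ---------------------------------------------------------------------------
# default parameter bundle: the published base case

.default_param_table <- function() {
  # name, base, low, high, distribution, units, one per row
  L <- list(
    # clinical (Key clinical data table)
    list("hr_chemo_vs_supportive",   0.77,   0.71,    0.83,    "beta",       "hazard ratio"),
    list("p_death_progressed",       0.086,  0.08,    0.093,   "beta",       "probability/cycle"),
    list("alk_prevalence",           0.065,  0.014,   0.116,   "beta",       "proportion"),
    list("body_surface_area",        1.72,   1.5,     1.9,     "triangular", "m2"),
    list("salvage_uptake",           0.566,  0.26,    0.72,    "beta",       "proportion"),
    list("post_progression_median_os", 5.4,  5.4,     5.4,     "fixed",      "months"),
    # Weibull PFS curves (no published ranges: fixed in both DSA and PSA)
    list("criz_weibull_scale",       0.0211, 0.0211,  0.0211,  "fixed",      "1/month^shape"),
    list("criz_weibull_shape",       1.5326, 1.5326,  1.5326,  "fixed",      ""),
    list("chemo_weibull_scale",      0.0663, 0.0663,  0.0663,  "fixed",      "1/unit^shape"),
    list("chemo_weibull_shape",      0.8604, 0.8604,  0.8604,  "fixed",      ""),
    # test characteristics
    list("ngs_sensitivity",          1,      0.95,    1,       "beta",       "probability"),
    list("ngs_specificity",          1,      0.95,    1,       "beta",       "probability"),
    list("pcr_sensitivity",          1,      0.95,    1,       "beta",       "probability"),
    list("pcr_specificity",          1,      0.95,    1,       "beta",       "probability"),
    # costs (2016 USD)
    list("cost_test_ngs",            1014.49, 869.57, 1159.42, "triangular", "USD/patient"),
    list("cost_test_pcr",            660.75,  440.50, 881.01,  "triangular", "USD/patient"),
    list("pemetrexed_per_500mg",     2083.97, 857.14, 2126.51, "triangular", "USD/500 mg"),
    list("chemo_other_per_cycle",    518.4,   388.8,  648,     "triangular", "USD/cycle"),
    list("crizotinib_per_day",       238.1,   119.05, 238.1,   "fixed",      "USD/day"),
    list("followup_per_cycle",       55.6,    41.7,   69.4,    "triangular", "USD/cycle"),
    list("salvage_per_cycle",        2352.7,  1921.1, 4383.3,  "triangular", "USD/cycle"),
    list("palliative_terminal",      2042.91, 793.65, 5456.19, "triangular", "USD/death"),
    list("supportive_per_cycle",     337.5,   158.7,  793.7,   "triangular", "USD/cycle"),
    list("sae_initial_chemo_per_cycle", 507.4, 189.7, 825.0,   "triangular", "USD/cycle"),
    # utilities (+-25% of the mean; the PFS upper bound is truncated at the
    # utility ceiling of 1)
    list("u_pfs",                    0.804,  0.603,   1,       "beta",       "utility"),
    list("u_progressed",             0.321,  0.24075, 0.40125, "beta",       "utility"),
    # discounting (range for one-way analysis only; an assumption, the
    # source states no range)
    list("annual_discount",          0.05,   0,       0.08,    "fixed",      "per year")
  )
  names(L) <- vapply(L, `[[`, "", 1L)
  L
}

#' Built-in base-case parameter bundle
#'
#' Returns the full model input bundle: every clinical, cost, utility and
#' test parameter at its published base value and range, the two Weibull
#' progression-free-survival curves, and the run settings (10-year horizon,
#' 5% annual discount, willingness-to-pay 32,000 USD/QALY) together with
#' the calibrated modelling conventions this package ships (cycle length,
#' per-curve time units, salvage duration, patient-assistance-program paid
#' days, test-cost allocation) — see the package vignette for how those
#' were chosen.
#'
#' @param pap Logical: is the crizotinib patient assistance program
#'   available?  Affects pricing only, never health outcomes.
#' @return An object of class `cea_parameters`: a list with elements
#'   `params` (named list of [parameter_spec()]), `run` (run settings) and
#'   the SAE disutility map `sae_disutilities` (all zero by default).
#' @examples
#' b <- default_parameters()
#' b$params$alk_prevalence
#' @export
default_parameters <- function(pap = TRUE) {
  tab <- .default_param_table()
  params <- lapply(tab, function(r)
    parameter_spec(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]]))
  run <- list(
    horizon_years = 10,
    cycle_days = .calibrated_defaults$cycle_days,
    days_per_month = 30,
    annual_discount = 0.05,
    wtp_per_qaly = 32000,
    chemo_max_cycles = 4,
    salvage_max_cycles = .calibrated_defaults$salvage_max_cycles,
    half_cycle_correction = FALSE,
    criz_time_unit = .calibrated_defaults$criz_time_unit,
    chemo_time_unit = .calibrated_defaults$chemo_time_unit,
    pap = list(enabled = isTRUE(pap),
               paid_days = .calibrated_defaults$pap_paid_days),
    test_cost_policy = .calibrated_defaults$test_cost_policy,
    pemetrexed_billing = "vial"
  )
  bundle <- structure(list(params = params, run = run,
                           sae_disutilities = numeric(0)),
                      class = "cea_parameters")
  validate_parameters(bundle)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("CEA parameter bundle:", length(x$params), "parameters\n")
  cat(sprintf("  horizon %g y | cycle %g d | discount %g | WTP %g USD/QALY\n",
              x$run$horizon_years, x$run$cycle_days, x$run$annual_discount,
              x$run$wtp_per_qaly))
  cat(sprintf("  PAP %s (paid days %g) | curve units: crizotinib %s, chemo %s\n",
              if (x$run$pap$enabled) "on" else "off", x$run$pap$paid_days,
              x$run$criz_time_unit, x$run$chemo_time_unit))
  for (p in x$params) print(p)
  invisible(x)
}

#' Base value of a named parameter
#'
#' @param bundle A `cea_parameters` bundle.
#' @param name Parameter name.
#' @return The base value (scalar).
#' @export
param_base <- function(bundle, name) {
  p <- bundle$params[[name]]
  if (is.null(p)) stop("unknown parameter '", name, "'; valid names: ",
                       paste(names(bundle$params), collapse = ", "),
                       call. = FALSE)
  p$base
}

#' Replace the base value of a named parameter
#'
#' Returns a modified copy; the input bundle is never mutated.
#'
#' @inheritParams param_base
#' @param value New base value (range is widened to include it if needed).
#' @return A new `cea_parameters` bundle.
#' @export
param_set <- function(bundle, name, value) {
  p <- bundle$params[[name]]
  if (is.null(p)) stop("unknown parameter '", name, "'; valid names: ",
                       paste(names(bundle$params), collapse = ", "),
                       call. = FALSE)
  bundle$params[[name]] <- parameter_spec(p$name, value,
                                          min(p$low, value), max(p$high, value),
                                          p$distribution, p$units)
  # the discount rate also lives in the run settings the engine reads
  if (name == "annual_discount") bundle$run$annual_discount <- value
  bundle
}

# the two PFS curves implied by the bundle, in their configured time units
bundle_curves <- function(bundle) {
  list(
    crizotinib = weibull_curve(param_base(bundle, "criz_weibull_scale"),
                               param_base(bundle, "criz_weibull_shape"),
                               bundle$run$criz_time_unit),
    chemo = weibull_curve(param_base(bundle, "chemo_weibull_scale"),
                          param_base(bundle, "chemo_weibull_shape"),
                          bundle$run$chemo_time_unit)
  )
}

validate_parameters <- function(bundle) {
  stopifnot(inherits(bundle, "cea_parameters"))
  for (p in bundle$params) {
    if (p$low > p$base || p$base > p$high)
      stop("parameter '", p$name, "' violates low <= base <= high", call. = FALSE)
    if (p$distribution == "beta" && (p$low < 0 || p$high > 1))
      stop("parameter '", p$name, "' marked beta outside [0, 1]", call. = FALSE)
  }
  probs <- c("p_death_progressed", "alk_prevalence", "salvage_uptake",
             "ngs_sensitivity", "ngs_specificity", "pcr_sensitivity",
             "pcr_specificity", "u_pfs", "u_progressed")
  for (nm in probs) {
    v <- param_base(bundle, nm)
    if (v < 0 || v > 1)
      stop("parameter '", nm, "' must lie in [0, 1], got ", v, call. = FALSE)
  }
  if (param_base(bundle, "hr_chemo_vs_supportive") <= 0)
    stop("hazard ratio must be > 0", call. = FALSE)
  if (param_base(bundle, "body_surface_area") <= 0)
    stop("body surface area must be > 0", call. = FALSE)
  if (param_base(bundle, "u_progressed") > param_base(bundle, "u_pfs"))
    stop("progressed-state utility cannot exceed progression-free utility",
         call. = FALSE)
  costs <- grep("^cost_|_per_cycle$|_per_day$|_per_500mg$|palliative",
                names(bundle$params), value = TRUE)
  for (nm in costs)
    if (param_base(bundle, nm) < 0)
      stop("cost parameter '", nm, "' must be >= 0", call. = FALSE)
  r <- bundle$run
  if (r$horizon_years <= 0) stop("horizon must be > 0", call. = FALSE)
  if (r$cycle_days <= 0) stop("cycle length must be > 0", call. = FALSE)
  if (r$annual_discount < 0 || r$annual_discount >= 1)
    stop("annual discount must lie in [0, 1)", call. = FALSE)
  if (!r$criz_time_unit %in% c("month", "week", "cycle") ||
      !r$chemo_time_unit %in% c("month", "week", "cycle"))
    stop("curve time units must be 'month', 'week' or 'cycle'", call. = FALSE)
  if (!isTRUE(r$pap$paid_days >= 0))
    stop("PAP paid_days must be >= 0", call. = FALSE)
  if (!r$test_cost_policy %in% c("positives", "all"))
    stop("test_cost_policy must be 'positives' or 'all'", call. = FALSE)
  if (!r$pemetrexed_billing %in% c("vial", "proportional"))
    stop("pemetrexed_billing must be 'vial' or 'proportional'", call. = FALSE)
  bundle
}

# ---------------------------------------------------------------------------
# configuration file I/O (flat YAML; sections clinical/costs/utilities/
# tests/run; each parameter entry either a scalar or {base, low, high,
# distribution})

.param_sections <- function() {
  list(
    clinical = c("hr_chemo_vs_supportive", "p_death_progressed",
                 "alk_prevalence", "body_surface_area", "salvage_uptake",
                 "post_progression_median_os", "criz_weibull_scale",
                 "criz_weibull_shape", "chemo_weibull_scale",
                 "chemo_weibull_shape"),
    tests = c("ngs_sensitivity", "ngs_specificity", "pcr_sensitivity",
              "pcr_specificity", "cost_test_ngs", "cost_test_pcr"),
    costs = c("pemetrexed_per_500mg", "chemo_other_per_cycle",
              "crizotinib_per_day", "followup_per_cycle", "salvage_per_cycle",
              "palliative_terminal", "supportive_per_cycle",
              "sae_initial_chemo_per_cycle"),
    utilities = c("u_pfs", "u_progressed"),
    run_params = "annual_discount"
  )
}

#' Load a parameter bundle from a YAML configuration file
#'
#' The file holds sections `clinical`, `tests`, `costs`, `utilities` and
#' `run`; every parameter entry is either a bare number (base value only)
#' or a map with keys `base`, `low`, `high`, `distribution`.  Anything not
#' given falls back to the built-in base-case default, so an empty file
#' reproduces [default_parameters()].  A fully commented reference
#' configuration ships at
#' `system.file("extdata", "paper_defaults.yaml", package = "alkcea")`.
#'
#' @param path Path to the YAML file.
#' @return A validated `cea_parameters` bundle.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bundle <- default_parameters()
  secs <- .param_sections()
  known_sections <- c(names(secs)[names(secs) != "run_params"], "run")
  for (sec in setdiff(names(cfg), known_sections))
    stop("unknown configuration section '", sec, "'", call. = FALSE)
  for (sec in intersect(names(cfg), names(secs))) {
    for (nm in names(cfg[[sec]])) {
      if (!nm %in% secs[[sec]])
        stop("unknown parameter '", nm, "' in section '", sec, "'",
             call. = FALSE)
      old <- bundle$params[[nm]]
      e <- cfg[[sec]][[nm]]
      if (is.numeric(e) && length(e) == 1L) {
        bundle$params[[nm]] <- parameter_spec(nm, e, min(old$low, e),
                                              max(old$high, e),
                                              old$distribution, old$units)
      } else if (is.list(e)) {
        base <- if (!is.null(e$base)) e$base else old$base
        bundle$params[[nm]] <- parameter_spec(
          nm, base,
          low = if (!is.null(e$low)) e$low else min(old$low, base),
          high = if (!is.null(e$high)) e$high else max(old$high, base),
          distribution = if (!is.null(e$distribution)) e$distribution else old$distribution,
          units = old$units)
      } else stop("parameter '", nm, "' must be a number or a {base, low, high, distribution} map",
                  call. = FALSE)
    }
  }
  if (!is.null(cfg$run)) {
    run_keys <- c("horizon_years", "cycle_days", "days_per_month",
                  "annual_discount", "wtp_per_qaly", "chemo_max_cycles",
                  "salvage_max_cycles", "half_cycle_correction",
                  "criz_time_unit", "chemo_time_unit", "test_cost_policy",
                  "pemetrexed_billing")
    for (nm in names(cfg$run)) {
      if (nm == "pap") {
        if (!is.null(cfg$run$pap$enabled)) bundle$run$pap$enabled <- isTRUE(cfg$run$pap$enabled)
        if (!is.null(cfg$run$pap$paid_days)) bundle$run$pap$paid_days <- cfg$run$pap$paid_days
      } else if (nm %in% run_keys) {
        bundle$run[[nm]] <- cfg$run[[nm]]
      } else stop("unknown run setting '", nm, "'", call. = FALSE)
    }
    if (!is.null(cfg$run$annual_discount)) {
      d <- cfg$run$annual_discount
      old <- bundle$params$annual_discount
      bundle$params$annual_discount <-
        parameter_spec("annual_discount", d, min(old$low, d),
                       max(old$high, d), old$distribution, old$units)
    }
  }
  validate_parameters(bundle)
}

#' Serialize a parameter bundle to YAML
#'
#' Writes every parameter as a full `{base, low, high, distribution}` map
#' plus the run settings, such that `load_config(save_config(b, f))`
#' reproduces `b` exactly.
#'
#' @param bundle A `cea_parameters` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(bundle, path) {
  validate_parameters(bundle)
  secs <- .param_sections()
  out <- list()
  for (sec in c("clinical", "tests", "costs", "utilities")) {
    out[[sec]] <- lapply(bundle$params[secs[[sec]]], function(p)
      list(base = p$base, low = p$low, high = p$high,
           distribution = p$distribution))
  }
  run <- bundle$run
  # keep the DSA range of the discount rate alongside its run value
  out$run <- run
  d <- bundle$params$annual_discount
  out$run$annual_discount <- d$base
  yaml::write_yaml(out, path)
  invisible(path)
}
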