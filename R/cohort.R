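#' Discount factor
#'
#' \eqn{(1 + r)^{-t}} for time `t` in years at annual rate `r`; equals 1 at
#' `t = 0` or `r = 0`.
#'
#' @param t_years Time in years (>= 0, vectorized).
#' @param annual_rate Annual discount rate (>= 0).
#' @return Discount multipliers in `(0, 1]`.
#' @export
discount_factor <- function(t_years, annual_rate) {
  stopifnot(is.numeric(t_years), is.numeric(annual_rate))
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (any(t_years < 0)) stop("time must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-t_years)
}

# cycle length expressed in a curve's time unit
cycle_length_in_unit <- function(time_unit, cycle_days, days_per_month) {
  switch(time_unit,
         month = cycle_days / days_per_month,
         week = cycle_days / 7,
         cycle = 1,
         stop("unknown time unit: ", time_unit, call. = FALSE))
}

#' Run the three-state Markov cohort for one progression-free-survival curve
#'
#' Propagates a cohort through the states progression-free -> progressed ->
#' dead over the model horizon.  Each cycle, the progression-free fraction
#' moves to the progressed state with the curve's time-dependent per-cycle
#' probability (the hazard is read off the Weibull curve on the cycle grid,
#' so the cohort's progression-free fraction reproduces the curve exactly),
#' and the progressed pool dies with the constant per-cycle probability
#' derived from the 5.4-month post-progression median survival.  Patients
#' who progress during a cycle spend on average half of it in the
#' progressed state, so half of the same-cycle arrivals are exposed to the
#' death hazard; there is no other progression-free -> dead pathway and no
#' backward transition.
#'
#' @param curve The subcohort's PFS [weibull_curve()].
#' @param bundle A `cea_parameters` bundle (run settings and the progressed
#'   state death probability).
#' @return A `cohort_trace`: a data frame with one row per cycle boundary
#'   (`floor(horizon_years * 365.25 / cycle_days) + 1` rows) and columns
#'   `cycle`, `time_years`, `pfs`, `progressed`, `dead`, `new_deaths`
#'   (deaths during the cycle ending at the row), `new_progressions`
#'   (arrivals into the progressed state at the row, after their same-cycle
#'   death draw) and `discount`.
#' @export
run_trace <- function(curve, bundle) {
  stopifnot(inherits(curve, "weibull_curve"),
            inherits(bundle, "cea_parameters"))
  run <- bundle$run
  n <- floor(run$horizon_years * 365.25 / run$cycle_days)
  if (n < 1) stop("horizon must span at least one cycle", call. = FALSE)
  dt <- cycle_length_in_unit(curve$time_unit, run$cycle_days,
                             run$days_per_month)
  cyc_years <- run$cycle_days / 365.25
  p_death <- param_base(bundle, "p_death_progressed")

  p_prog <- per_cycle_transition_prob(curve, 0:(n - 1), cycle_length = dt)

  pfs <- numeric(n + 1); pd <- numeric(n + 1); dead <- numeric(n + 1)
  new_deaths <- numeric(n + 1); new_prog <- numeric(n + 1)
  pfs[1] <- 1
  for (k in 1:n) {
    moved <- pfs[k] * p_prog[k]
    # same-cycle arrivals spend on average half the cycle in the
    # progressed state, so half of them are exposed to the death hazard
    deaths <- (pd[k] + moved / 2) * p_death
    pfs[k + 1] <- pfs[k] - moved
    pd[k + 1] <- pd[k] + moved - deaths
    dead[k + 1] <- dead[k] + deaths
    new_deaths[k + 1] <- deaths
    new_prog[k + 1] <- moved * (1 - p_death / 2)
  }
  t_years <- (0:n) * cyc_years
  trace <- data.frame(cycle = 0:n, time_years = t_years, pfs = pfs,
                      progressed = pd, dead = dead, new_deaths = new_deaths,
                      new_progressions = new_prog,
                      discount = discount_factor(t_years, run$annual_discount))
  structure(trace, class = c("cohort_trace", "data.frame"),
            p_death = p_death, cycle_days = run$cycle_days,
            cyc_years = cyc_years)
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x) - 1L
  cat(sprintf("Markov cohort trace: %d cycles of %g days (%.2f years)\n",
              n, attr(x, "cycle_days"), x$time_years[n + 1L]))
  cat(sprintf("  final occupancy: PFS %.4f | progressed %.4f | dead %.4f\n",
              x$pfs[n + 1L], x$progressed[n + 1L], x$dead[n + 1L]))
  invisible(x)
}

# fraction of cycle k's progressed occupancy that is within its first
# `salvage_max` cycles in the state (rows are 1-based; k is a row index)
salvage_occupancy <- function(trace, salvage_max) {
  p_death <- attr(trace, "p_death")
  n_rows <- nrow(trace)
  arr <- trace$new_progressions
  sal <- numeric(n_rows)
  if (salvage_max < 1) return(sal)
  # arrivals at row j occupy salvage cycles j .. j + salvage_max - 1
  for (j in seq_len(n_rows)) {
    if (arr[j] <= 0) next
    ages <- 0:(salvage_max - 1)
    rows <- j + ages
    keep <- rows <= n_rows
    sal[rows[keep]] <- sal[rows[keep]] + arr[j] * (1 - p_death)^(ages[keep])
  }
  sal
}

#' Accrue discounted costs, QALYs and life-years over a cohort trace
#'
#' Per cycle, state-residence quantities are taken from the start-of-cycle
#' occupancy (or the mid-cycle average when the half-cycle correction is
#' on) and discounted at the cycle-start time:
#' \itemize{
#'   \item progression-free state: drug cost (chemotherapy: whole-vial
#'     pemetrexed at 500 mg/m2 for the body surface area plus the
#'     per-cycle backbone and SAE management costs, for the first
#'     `chemo_max_cycles` cycles only; crizotinib: the daily price times
#'     days in the cycle, truncated by the patient-assistance-program paid
#'     days when PAP is on) plus routine follow-up;
#'   \item progressed state: for the first `salvage_max_cycles` cycles in
#'     the state a salvage-uptake-weighted mix of salvage chemotherapy and
#'     supportive care, supportive care thereafter;
#'   \item dying patients incur the terminal palliative cost once, at the
#'     cycle of death;
#'   \item QALYs weight residence by the state utilities (0.804 / 0.321),
#'     minus any configured SAE disutility during the initial chemotherapy
#'     cycles.
#' }
#'
#' @param trace A [run_trace()] result.
#' @param treatment `"chemo"` or `"crizotinib"` (pricing context of the
#'   progression-free state).
#' @param bundle A `cea_parameters` bundle.
#' @param pap Optional logical overriding the bundle's PAP flag.
#' @return An `accrual_result` list: `cost`, `qalys`, `pf_ly`, `overall_ly`
#'   (discounted) and the undiscounted twins `cost_undisc`, `qalys_undisc`,
#'   `pf_ly_undisc`, `overall_ly_undisc`.
#' @export
accrue <- function(trace, treatment = c("chemo", "crizotinib"), bundle,
                   pap = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(bundle, "cea_parameters"))
  run <- bundle$run
  pap_on <- if (is.null(pap)) run$pap$enabled else isTRUE(pap)
  n <- nrow(trace) - 1L
  cyc_years <- attr(trace, "cyc_years")
  cycle_days <- attr(trace, "cycle_days")
  hcc <- isTRUE(run$half_cycle_correction)

  pfs <- trace$pfs; pd <- trace$progressed
  occ_pfs <- if (hcc) (pfs[1:n] + pfs[2:(n + 1)]) / 2 else pfs[1:n]
  occ_pd <- if (hcc) (pd[1:n] + pd[2:(n + 1)]) / 2 else pd[1:n]
  df <- trace$discount[1:n]
  k <- 0:(n - 1)

  # progression-free drug + follow-up
  if (treatment == "crizotinib") {
    paid_days <- if (pap_on) run$pap$paid_days else Inf
    days_paid <- pmax(0, pmin(cycle_days, paid_days - k * cycle_days))
    drug <- param_base(bundle, "crizotinib_per_day") * days_paid
  } else {
    bsa <- param_base(bundle, "body_surface_area")
    vial_price <- param_base(bundle, "pemetrexed_per_500mg")
    dose_mg <- 500 * bsa
    pem <- if (run$pemetrexed_billing == "vial")
      ceiling(dose_mg / 500) * vial_price else dose_mg / 500 * vial_price
    per_cycle <- pem + param_base(bundle, "chemo_other_per_cycle") +
      param_base(bundle, "sae_initial_chemo_per_cycle")
    drug <- ifelse(k < run$chemo_max_cycles, per_cycle, 0)
  }
  pfs_cost <- occ_pfs * (drug + param_base(bundle, "followup_per_cycle"))

  # progressed-state costs, split by time in state
  uptake <- param_base(bundle, "salvage_uptake")
  c_sal <- param_base(bundle, "salvage_per_cycle")
  c_sup <- param_base(bundle, "supportive_per_cycle")
  sal_raw <- salvage_occupancy(trace, run$salvage_max_cycles)[1:n]
  sal_frac <- ifelse(pd[1:n] > 0, pmin(1, sal_raw / pd[1:n]), 0)
  sal_occ <- occ_pd * sal_frac
  pd_cost <- sal_occ * (uptake * c_sal + (1 - uptake) * c_sup) +
    (occ_pd - sal_occ) * c_sup

  # terminal palliative cost on the death transition
  deaths_in_cycle <- trace$new_deaths[2:(n + 1)]
  death_cost <- deaths_in_cycle * param_base(bundle, "palliative_terminal")

  cost_stream <- pfs_cost + pd_cost + death_cost

  u_pfs <- param_base(bundle, "u_pfs")
  u_pd <- param_base(bundle, "u_progressed")
  disutil <- sum(bundle$sae_disutilities)
  sae_decrement <- if (treatment == "chemo" && disutil > 0)
    ifelse(k < run$chemo_max_cycles, disutil * occ_pfs, 0) else 0
  qaly_stream <- (occ_pfs * u_pfs + occ_pd * u_pd - sae_decrement) * cyc_years
  pfly_stream <- occ_pfs * cyc_years
  ly_stream <- (occ_pfs + occ_pd) * cyc_years

  structure(list(
    cost = sum(df * cost_stream),
    qalys = sum(df * qaly_stream),
    pf_ly = sum(df * pfly_stream),
    overall_ly = sum(df * ly_stream),
    cost_undisc = sum(cost_stream),
    qalys_undisc = sum(qaly_stream),
    pf_ly_undisc = sum(pfly_stream),
    overall_ly_undisc = sum(ly_stream)
  ), class = "accrual_result")
}

#' @export
print.accrual_result <- function(x, ...) {
  cat(sprintf("discounted:   cost %10.2f | QALYs %.4f | PF LY %.4f | LY %.4f\n",
              x$cost, x$qalys, x$pf_ly, x$overall_ly))
  cat(sprintf("undiscounted: cost %10.2f | QALYs %.4f | PF LY %.4f | LY %.4f\n",
              x$cost_undisc, x$qalys_undisc, x$pf_ly_undisc,
              x$overall_ly_undisc))
  invisible(x)
}

#' Export / import a cohort trace as CSV
#'
#' Full-precision CSV round trip of the per-cycle trace.
#'
#' @param trace A `cohort_trace`.
#' @param path CSV file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   data frame (plain, without engine attributes).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- as.data.frame(trace)
  for (col in names(df)) if (is.numeric(df[[col]]))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
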