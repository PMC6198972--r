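#' Test-and-treat strategy specification
#'
#' A strategy is either the control arm (no testing, standard chemotherapy
#' for everyone) or an ALK-testing arm (NGS panel or multiplex PCR) in
#' which test-positive patients receive crizotinib and test-negative
#' patients receive chemotherapy.
#'
#' @param test `"none"` (control), `"ngs"` or `"pcr"`.
#' @param name Display label; defaults to a standard name per test.
#' @param pap Optional logical overriding the bundle's patient assistance
#'   program flag for this strategy; `NULL` uses the bundle setting.
#' @return An object of class `strategy_spec`.
#' @examples
#' strategy_spec("ngs")
#' strategy_spec("none")
#' @export
strategy_spec <- function(test = c("none", "ngs", "pcr"), name = NULL,
                          pap = NULL) {
  test <- match.arg(test)
  if (is.null(name))
    name <- switch(test, none = "control", ngs = "NGS panel",
                   pcr = "multiplex PCR")
  structure(list(name = name, test = test, pap = pap),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("strategy '%s' (test: %s%s)\n", x$name, x$test,
              if (is.null(x$pap)) "" else if (x$pap) ", PAP on" else ", PAP off"))
  invisible(x)
}

# test characteristics + per-patient cost for a strategy, from the bundle
test_characteristics <- function(spec, bundle) {
  switch(spec$test,
         none = list(name = "none", sensitivity = 1, specificity = 1, cost = 0),
         ngs = list(name = "ngs",
                    sensitivity = param_base(bundle, "ngs_sensitivity"),
                    specificity = param_base(bundle, "ngs_specificity"),
                    cost = param_base(bundle, "cost_test_ngs")),
         pcr = list(name = "pcr",
                    sensitivity = param_base(bundle, "pcr_sensitivity"),
                    specificity = param_base(bundle, "pcr_specificity"),
                    cost = param_base(bundle, "cost_test_pcr")))
}

#' Expand a strategy into weighted subcohorts
#'
#' Applies the diagnostic 2x2 arithmetic: with ALK prevalence \eqn{\pi},
#' sensitivity \eqn{se} and specificity \eqn{sp}, the tested cohort splits
#' into true positives (\eqn{\pi \cdot se}, crizotinib, crizotinib PFS
#' curve), false negatives (\eqn{\pi(1-se)}, chemotherapy), true negatives
#' (\eqn{(1-\pi)sp}, chemotherapy) and false positives
#' (\eqn{(1-\pi)(1-sp)}, crizotinib priced as treatment but following the
#' supportive-care PFS curve, since crizotinib gives ALK-negative patients
#' no benefit).  The control strategy is a single untested chemotherapy
#' subcohort of weight 1 and zero test cost.
#'
#' @param spec A [strategy_spec()].
#' @param prevalence ALK-rearrangement prevalence in `[0, 1]`.
#' @param bundle A `cea_parameters` bundle (supplies test characteristics
#'   and costs).
#' @return A list with `subcohorts` (data frame: `label`, `weight`,
#'   `treatment`, `pfs_curve_role`) and `test_cost` (per tested patient).
#'   Weights sum to 1.
#' @export
expand_strategy <- function(spec, prevalence, bundle) {
  stopifnot(inherits(spec, "strategy_spec"))
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  tc <- test_characteristics(spec, bundle)
  if (tc$name == "none") {
    sub <- data.frame(label = "untested", weight = 1, treatment = "chemo",
                      pfs_curve_role = "chemo", stringsAsFactors = FALSE)
    return(list(subcohorts = sub, test_cost = 0))
  }
  se <- tc$sensitivity; sp <- tc$specificity
  if (se < 0 || se > 1 || sp < 0 || sp > 1)
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sub <- data.frame(
    label = c("TP", "FN", "TN", "FP"),
    weight = c(prevalence * se, prevalence * (1 - se),
               (1 - prevalence) * sp, (1 - prevalence) * (1 - sp)),
    treatment = c("crizotinib", "chemo", "chemo", "crizotinib"),
    pfs_curve_role = c("crizotinib", "chemo", "chemo", "supportive"),
    stringsAsFactors = FALSE)
  stopifnot(abs(sum(sub$weight) - 1) < 1e-12)
  list(subcohorts = sub, test_cost = tc$cost)
}

#' Supportive-care PFS curve from the chemotherapy curve
#'
#' Constructs the supportive-care survival invoked for false-positive
#' patients by applying the published hazard ratio of chemotherapy versus
#' supportive care (0.77) in the proportional-hazards direction that makes
#' supportive care worse: \eqn{S_{supp} = S_{chemo}^{1/hr}}, i.e. the
#' Weibull scale is divided by the hazard ratio.
#'
#' @param chemo_curve The chemotherapy [weibull_curve()].
#' @param hr Hazard ratio of chemotherapy vs supportive care, in `(0, 1]`;
#'   values above 1 reverse the direction of benefit and raise a warning.
#' @return A `weibull_curve` with `scale / hr`, same shape and unit.
#' @export
supportive_pfs_curve <- function(chemo_curve, hr) {
  stopifnot(inherits(chemo_curve, "weibull_curve"), is.numeric(hr),
            length(hr) == 1L)
  if (hr <= 0) stop("hazard ratio must be > 0", call. = FALSE)
  if (hr > 1)
    warning("hazard ratio > 1 reverses the direction of benefit ",
            "(supportive care would outperform chemotherapy)", call. = FALSE)
  weibull_curve(chemo_curve$scale / hr, chemo_curve$shape,
                chemo_curve$time_unit)
}

# resolve a subcohort's pfs_curve_role to an actual curve
role_curve <- function(role, bundle) {
  curves <- bundle_curves(bundle)
  switch(role,
         crizotinib = curves$crizotinib,
         chemo = curves$chemo,
         supportive = supportive_pfs_curve(
           curves$chemo, param_base(bundle, "hr_chemo_vs_supportive")),
         stop("unknown PFS curve role: ", role, call. = FALSE))
}
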