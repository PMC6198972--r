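#' Parametric Weibull survival curve
#'
#' Constructs a Weibull survival curve in the actuarial parameterization
#' \eqn{S(t) = \exp(-\lambda t^\gamma)}, the form conventionally used for
#' progression-free-survival extrapolation in cost-effectiveness models.
#' `scale` is \eqn{\lambda} and `shape` is \eqn{\gamma}; `shape > 1` means
#' an increasing progression hazard over time.
#'
#' @param scale Positive scale parameter \eqn{\lambda}.
#' @param shape Positive shape parameter \eqn{\gamma}.
#' @param time_unit Unit in which `t` is measured: `"month"`, `"week"` or
#'   `"cycle"` (one model cycle).
#' @param fit_r2 Optional coefficient of determination carried over from a
#'   Kaplan-Meier fit (see [fit_weibull()]).
#' @return An object of class `weibull_curve`.
#' @examples
#' crz <- weibull_curve(0.0211, 1.5326)   # crizotinib PFS, monthly time
#' weibull_survival(crz, 10)
#' median_survival(crz)
#' @seealso [weibull_survival()], [fit_weibull()], [recalibrate_scale()]
#' @export
weibull_curve <- function(scale, shape, time_unit = c("month", "week", "cycle"),
                          fit_r2 = NULL) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  if (shape <= 0) stop("`shape` must be > 0", call. = FALSE)
  if (!is.null(fit_r2)) {
    stopifnot(is.numeric(fit_r2), length(fit_r2) == 1L)
    if (fit_r2 < 0 || fit_r2 > 1) stop("`fit_r2` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(scale = scale, shape = shape, time_unit = time_unit,
                 fit_r2 = fit_r2),
            class = "weibull_curve")
}

#' @export
print.weibull_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Weibull survival curve  S(t) = exp(-%s t^%s), t in %ss\n",
              format(x$scale, digits = digits),
              format(x$shape, digits = digits), x$time_unit))
  cat(sprintf("  median survival: %s %ss\n",
              format(median_survival(x), digits = digits), x$time_unit))
  if (!is.null(x$fit_r2))
    cat(sprintf("  r-squared of KM fit: %s\n", format(x$fit_r2, digits = digits)))
  invisible(x)
}

#' @export
coef.weibull_curve <- function(object, ...) {
  c(scale = object$scale, shape = object$shape)
}

#' Survival probability of a Weibull curve
#'
#' Evaluates \eqn{S(t) = \exp(-\lambda t^\gamma)} at times `t` expressed in
#' the curve's own time unit.
#'
#' @param curve A [weibull_curve()].
#' @param t Vector of non-negative times.
#' @return Survival probabilities in `(0, 1]`; exactly 1 at `t = 0`.
#' @export
weibull_survival <- function(curve, t) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(t))
  if (any(t < 0)) stop("survival time `t` must be >= 0", call. = FALSE)
  exp(-curve$scale * t^curve$shape)
}

#' @export
predict.weibull_curve <- function(object, t, ...) weibull_survival(object, t)

#' @export
plot.weibull_curve <- function(x, tmax = NULL, n = 200, ...) {
  if (is.null(tmax)) tmax <- 4 * median_survival(x)
  tt <- seq(0, tmax, length.out = n)
  plot(tt, weibull_survival(x, tt), type = "l",
       xlab = sprintf("time (%ss)", x$time_unit), ylab = "S(t)",
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of leaving the progression-free state during the cycle that
#' starts at time `cycle_index * cycle_length` (both in the curve's time
#' unit): \eqn{1 - S(t + \Delta)/S(t)}.  The hazard is taken
#' time-dependent, so the cohort reproduces the fitted curve exactly
#' (telescoping product of the per-cycle survival fractions).
#'
#' @param curve A [weibull_curve()].
#' @param cycle_index Non-negative integer cycle index (vectorized).
#' @param cycle_length Length of one model cycle in the curve's time unit
#'   (default 1, i.e. one curve unit per cycle).
#' @return Probabilities in `[0, 1)`: non-decreasing in `cycle_index` when
#'   `shape > 1`, non-increasing when `shape < 1`, constant for the
#'   exponential special case `shape = 1`.
#' @export
per_cycle_transition_prob <- function(curve, cycle_index, cycle_length = 1) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(cycle_index),
            is.numeric(cycle_length), cycle_length > 0)
  if (any(cycle_index < 0)) stop("`cycle_index` must be >= 0", call. = FALSE)
  t0 <- cycle_index * cycle_length
  # conditional probability via the cumulative-hazard increment; stable
  # where S itself underflows
  -expm1(-curve$scale * ((t0 + cycle_length)^curve$shape - t0^curve$shape))
}

#' Proportional-hazards transform of a survival probability
#'
#' Applies a hazard ratio to a survival probability: \eqn{S^{hr}}.  Used to
#' derive the supportive-care survival from the chemotherapy curve via the
#' published HR of 0.77 (chemotherapy vs supportive care).
#'
#' @param s Survival probabilities in `(0, 1]`.
#' @param hr Positive hazard ratio; `hr = 1` is the identity.
#' @return `s^hr`.
#' @export
apply_hazard_ratio <- function(s, hr) {
  stopifnot(is.numeric(s), is.numeric(hr), length(hr) == 1L)
  if (hr <= 0) stop("hazard ratio must be > 0", call. = FALSE)
  if (any(s <= 0 | s > 1)) stop("survival `s` must lie in (0, 1]", call. = FALSE)
  s^hr
}

#' Median survival time of a Weibull curve
#'
#' Closed form \eqn{(\ln 2 / \lambda)^{1/\gamma}} in the curve's time unit.
#'
#' @param curve A [weibull_curve()].
#' @return Median survival time.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "weibull_curve"))
  (log(2) / curve$scale)^(1 / curve$shape)
}

#' Constant per-cycle death probability from a median survival
#'
#' Converts a median overall survival (months) into the per-cycle death
#' probability of the exponential distribution with that median:
#' \eqn{1 - 0.5^{c/(m d)}} with cycle length `c` days and `d` days per
#' month.  With the published 5.4-month post-progression median, 21-day
#' cycles and 30-day months this reproduces the tabulated 0.086.
#'
#' @param median_months Median survival in months (> 0).
#' @param cycle_days Model cycle length in days (> 0).
#' @param days_per_month Days per month convention (> 0), default 30.
#' @return A probability in `(0, 1)`.
#' @examples
#' cycle_prob_from_median(5.4, 21, 30)   # 0.086
#' @export
cycle_prob_from_median <- function(median_months, cycle_days, days_per_month = 30) {
  stopifnot(is.numeric(median_months), is.numeric(cycle_days),
            is.numeric(days_per_month))
  if (median_months <= 0 || cycle_days <= 0 || days_per_month <= 0)
    stop("all arguments must be > 0", call. = FALSE)
  1 - 0.5^(cycle_days / (median_months * days_per_month))
}

#' Fit a Weibull curve to digitized Kaplan-Meier points
#'
#' Least-squares fit of the log-log linearization: regressing
#' \eqn{\log(-\log S_i)} on \eqn{\log t_i} gives `shape` as the slope and
#' `scale` as `exp(intercept)`.  The regression is weighted by
#' \eqn{(\log S_i)^2}: digitization error is approximately multiplicative
#' on survival, and by the delta method the induced variance of
#' \eqn{\log(-\log S)} is proportional to \eqn{1/(\log S)^2}, which would
#' otherwise let the near-1 early points dominate the fit.  The regression
#' r-squared is the fit diagnostic reported alongside the curve, matching
#' how published cost-effectiveness models report an adjusted r-squared
#' for their Kaplan-Meier extrapolations.  Noise-free Weibull input is
#' recovered exactly (r-squared 1).
#'
#' @param points A data frame with columns `time` (> 0, strictly
#'   increasing) and `survival` (in `(0, 1)`, the open interval: 0 and 1
#'   have no log-log image), e.g. from [read_km_points()] or
#'   [generate_km_points()].
#' @param time_unit Time unit the `time` column is expressed in.
#' @return A `weibull_fit` object (subclass of `weibull_curve`) with the
#'   fitted `scale`, `shape` and `fit_r2`, plus the underlying `lm` fit and
#'   the points used.
#' @examples
#' pts <- data.frame(time = 1:30,
#'                   survival = exp(-0.0211 * (1:30)^1.5326))
#' fit_weibull(pts)
#' @export
fit_weibull <- function(points, time_unit = c("month", "week", "cycle")) {
  time_unit <- match.arg(time_unit)
  points <- validate_km_points(points, allow_boundary = FALSE)
  if (nrow(points) < 3L)
    stop("Weibull fit needs at least 3 usable Kaplan-Meier points, got ",
         nrow(points), call. = FALSE)
  x <- log(points$time)
  y <- log(-log(points$survival))
  w <- log(points$survival)^2
  reg <- stats::lm(y ~ x, weights = w)
  # a noise-free curve is an exact fit; lm's perfect-fit warning is expected
  r2 <- suppressWarnings(summary(reg)$r.squared)
  curve <- weibull_curve(scale = exp(unname(stats::coef(reg)[1L])),
                         shape = unname(stats::coef(reg)[2L]),
                         time_unit = time_unit, fit_r2 = r2)
  curve$lm <- reg
  curve$points <- points
  class(curve) <- c("weibull_fit", class(curve))
  curve
}

#' @export
print.weibull_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Weibull fit to %d Kaplan-Meier points (log-log least squares)\n",
              nrow(x$points)))
  NextMethod()
}

#' @export
summary.weibull_fit <- function(object, ...) {
  structure(list(curve = object, lm_summary = summary(object$lm)),
            class = "summary.weibull_fit")
}

#' @export
print.summary.weibull_fit <- function(x, ...) {
  print(x$curve)
  cat("\nLog-log regression:\n")
  print(stats::coef(x$lm_summary))
  invisible(x)
}

#' @export
residuals.weibull_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.weibull_fit <- function(x, ...) {
  tt <- x$points$time
  plot(tt, x$points$survival, xlab = sprintf("time (%ss)", x$time_unit),
       ylab = "S(t)", ylim = c(0, 1), ...)
  grid_t <- seq(min(tt), max(tt), length.out = 200)
  lines(grid_t, weibull_survival(x, grid_t))
  invisible(x)
}

#' Rescale a Weibull curve to a target median survival
#'
#' Keeps the shape and solves the scale so the median equals
#' `target_median`: \eqn{\lambda = \ln 2 / m^\gamma}.  This is the escape
#' hatch for reconciling a printed (scale, shape) pair with a trial median
#' reported in a different time unit.
#'
#' @param curve A [weibull_curve()].
#' @param target_median Target median survival (> 0) in the curve's unit.
#' @return A new `weibull_curve` with `median_survival()` equal to
#'   `target_median` to machine precision.
#' @export
recalibrate_scale <- function(curve, target_median) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(target_median))
  if (target_median <= 0) stop("`target_median` must be > 0", call. = FALSE)
  weibull_curve(scale = log(2) / target_median^curve$shape,
                shape = curve$shape, time_unit = curve$time_unit)
}

# shared KM-point validation; boundary survival values (0 or 1) are either
# rejected (fitting) or merely clipped upstream (synthetic generation)
validate_km_points <- function(points, allow_boundary = FALSE) {
  if (!is.data.frame(points) || !all(c("time", "survival") %in% names(points)))
    stop("Kaplan-Meier points must be a data frame with columns `time` and `survival`",
         call. = FALSE)
  points <- points[, c("time", "survival")]
  if (any(points$time <= 0)) stop("Kaplan-Meier times must be > 0", call. = FALSE)
  if (is.unsorted(points$time, strictly = TRUE))
    stop("Kaplan-Meier times must be strictly increasing", call. = FALSE)
  if (any(diff(points$survival) > 1e-12))
    stop("Kaplan-Meier survival must be non-increasing", call. = FALSE)
  bad <- points$survival <= 0 | points$survival >= 1
  if (!allow_boundary && any(bad))
    stop("survival values must lie strictly in (0, 1); offending times: ",
         paste(points$time[bad], collapse = ", "), call. = FALSE)
  points
}

#' Read or write digitized Kaplan-Meier points
#'
#' Two-column CSV interchange (`time,survival`, header row) for digitized
#' Kaplan-Meier coordinates, times in the curve's declared unit.
#'
#' @param path CSV file path.
#' @return `read_km_points()` returns a validated data frame with columns
#'   `time` and `survival`.
#' @export
read_km_points <- function(path) {
  pts <- utils::read.csv(path)
  validate_km_points(pts, allow_boundary = TRUE)
}

#' @rdname read_km_points
#' @param points Data frame of Kaplan-Meier points.
#' @export
write_km_points <- function(points, path) {
  points <- validate_km_points(points, allow_boundary = TRUE)
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}
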