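#' Generate pseudo-digitized Kaplan-Meier points from a known Weibull curve
#'
#' Emulates the digitization of a published Kaplan-Meier curve: evaluates
#' \eqn{S(t) = \exp(-\lambda t^\gamma)} on the given time grid and applies
#' multiplicative log-normal noise (\eqn{S_i \exp(\epsilon_i)},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}), which keeps survival positive and
#' lets the error scale with the curve height as digitization error does.
#' Values are clipped to `(0, 1)` and forced non-increasing by a cumulative
#' minimum.  Deterministic given `seed`.
#'
#' @param curve A [weibull_curve()].
#' @param times Strictly increasing positive evaluation times in the
#'   curve's unit.
#' @param noise_sd Log-scale noise standard deviation (>= 0; 0 gives points
#'   exactly on the curve).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `time` and `survival`, valid input for
#'   [fit_weibull()].
#' @examples
#' crz <- weibull_curve(0.0211, 1.5326)
#' pts <- generate_km_points(crz, 1:30, noise_sd = 0.01, seed = 1)
#' fit_weibull(pts)
#' @export
generate_km_points <- function(curve, times, noise_sd = 0, seed = 1) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(times),
            is.numeric(noise_sd), noise_sd >= 0)
  if (any(times <= 0)) stop("evaluation times must be > 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("evaluation times must be strictly increasing", call. = FALSE)
  s <- weibull_survival(curve, times)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    s <- s * exp(stats::rnorm(length(s), 0, noise_sd))
  }
  eps <- 1e-12
  s <- pmin(pmax(s, eps), 1 - eps)
  s <- cummin(s)                      # digitized curves cannot rise
  data.frame(time = times, survival = s)
}

#' Generate a random valid parameter bundle
#'
#' Draws every ranged parameter uniformly within its published range
#' (probabilities clipped to `[0, 1]`; the progressed-state utility is kept
#' at or below the progression-free utility so the bundle always
#' validates).  Intended for property-style fuzzing of the pipeline, not
#' for inference.  Deterministic given `seed`.
#'
#' @param seed Integer RNG seed.
#' @param pap Patient-assistance-program flag passed through to
#'   [default_parameters()].
#' @return A validated `cea_parameters` bundle.
#' @export
generate_parameter_bundle <- function(seed = 1, pap = TRUE) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  bundle <- default_parameters(pap = pap)
  for (nm in names(bundle$params)) {
    p <- bundle$params[[nm]]
    if (p$low < p$high)
      bundle$params[[nm]]$base <- stats::runif(1L, p$low, p$high)
  }
  if (bundle$params$u_progressed$base > bundle$params$u_pfs$base)
    bundle$params$u_progressed$base <- bundle$params$u_pfs$base
  bundle$run$annual_discount <- bundle$params$annual_discount$base
  validate_parameters(bundle)
}
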