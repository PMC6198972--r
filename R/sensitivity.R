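#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling on `[low, high]` with mode `mode`; used for the
#' cost parameters in probabilistic sensitivity analysis (mode = base-case
#' value, bounds = published range).  The degenerate case
#' `low == mode == high` returns the constant.
#'
#' @param n Number of draws.
#' @param low,mode,high Triangle parameters, `low <= mode <= high`.
#' @return `n` draws with support exactly `[low, high]` and expectation
#'   `(low + mode + high) / 3`.
#' @export
sample_triangular <- function(n, low, mode, high) {
  if (!(low <= mode && mode <= high))
    stop("need low <= mode <= high", call. = FALSE)
  if (low == high) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Draw from a beta distribution parameterized by mean and range
#'
#' Method-of-moments beta with mean `base` and standard deviation
#' `(high - low) / 4` (the published range read as an approximate 95%
#' interval), used for probabilities, proportions and utilities in the
#' probabilistic sensitivity analysis.  A degenerate range returns the
#' constant.  When the implied moments admit no beta distribution
#' (`sd^2 >= mean (1 - mean)`, e.g. a parameter whose base value sits on
#' the boundary such as a test sensitivity of 1), the draw falls back to
#' uniform on `[low, high]` with a warning.
#'
#' @param n Number of draws.
#' @param base Mean, in `[0, 1]`.
#' @param low,high Range, `0 <= low <= base <= high <= 1`.
#' @return `n` draws in `[0, 1]`.
#' @export
sample_beta_from_range <- function(n, base, low, high) {
  if (!(0 <= low && low <= base && base <= high && high <= 1))
    stop("need 0 <= low <= base <= high <= 1", call. = FALSE)
  if (low == high) return(rep(base, n))
  s <- (high - low) / 4
  if (s^2 >= base * (1 - base)) {
    warning(sprintf(paste0("mean %g and sd %g admit no beta distribution; ",
                           "falling back to uniform on [%g, %g]"),
                    base, s, low, high), call. = FALSE)
    return(stats::runif(n, low, high))
  }
  nu <- base * (1 - base) / s^2 - 1
  stats::rbeta(n, shape1 = base * nu, shape2 = (1 - base) * nu)
}

# How a parameter is actually sampled in the PSA.  Beta parameters whose
# base value sits *on* a range boundary (test sensitivity/specificity of 1
# with interval 0.95-1) admit no mean-parameterized beta; their published
# interval is a confidence interval, so they are drawn from the
# boundary-mode beta whose 2.5% quantile is the opposite bound
# (Beta(alpha, 1) with alpha = log(0.025)/log(low) for an upper-boundary
# base, mirrored for a lower-boundary base).  An off-boundary mean whose
# implied sd still admits no beta falls back to uniform on the range.
psa_sampler_info <- function(p) {
  if (p$distribution == "fixed" || p$low == p$high) return("fixed")
  if (p$distribution == "triangular") return("triangular")
  s <- (p$high - p$low) / 4
  if (s^2 < p$base * (1 - p$base)) return("beta")
  if (p$base == p$high && p$low > 0 && p$low < 1) return("beta_boundary_hi")
  if (p$base == p$low && p$high > 0 && p$high < 1) return("beta_boundary_lo")
  "uniform"
}

# one PSA draw for a single parameter_spec
sample_parameter <- function(p) {
  switch(psa_sampler_info(p),
         fixed = p$base,
         triangular = sample_triangular(1L, p$low, p$base, p$high),
         beta = sample_beta_from_range(1L, p$base, p$low, p$high),
         beta_boundary_hi = stats::rbeta(1L, log(0.025) / log(p$low), 1),
         beta_boundary_lo = 1 - stats::rbeta(1L, log(0.025) / log(1 - p$high), 1),
         uniform = stats::runif(1L, p$low, p$high))
}

# names of parameters that vary in the PSA, with their resolved sampler
psa_sampled_parameters <- function(bundle) {
  nm <- names(bundle$params)
  keep <- vapply(bundle$params, function(p)
    p$distribution != "fixed" && p$low < p$high, TRUE)
  nm[keep]
}

#' Monte-Carlo probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter from its assigned distribution
#' (triangular for ranged costs, method-of-moments beta for probabilities,
#' proportions and utilities, uniform fallback where the beta is
#' degenerate; the crizotinib daily price is fixed by design and scenario-
#' analysed through the PAP switch instead), evaluates all strategies on
#' the *same* draw (common random parameters), and records each strategy's
#' discounted cost and QALYs.  Output is reproducible: identical
#' `(seed, n)` give identical samples.
#'
#' @param bundle A `cea_parameters` bundle.
#' @param strategies List of [strategy_spec()]; default control, NGS, PCR.
#' @param n Number of simulations (published analysis: 1,000).
#' @param seed Integer RNG seed.
#' @return A `cea_psa`: `samples` (data frame `draw`, `strategy`, `cost`,
#'   `qalys`), `parameters` (data frame of the sampled values per draw),
#'   `wtp`, `seed`, `n`.
#' @export
run_psa <- function(bundle, strategies = list(strategy_spec("none"),
                                              strategy_spec("ngs"),
                                              strategy_spec("pcr")),
                    n = 1000, seed = 20161023) {
  stopifnot(inherits(bundle, "cea_parameters"), n >= 1)
  sampled <- psa_sampled_parameters(bundle)
  # flag irregular sampler resolutions once, not per draw
  for (nm in sampled) {
    p <- bundle$params[[nm]]
    info <- psa_sampler_info(p)
    if (info %in% c("beta_boundary_hi", "beta_boundary_lo"))
      message("PSA: parameter '", nm, "' has a boundary mean; sampled from ",
              "the boundary-mode beta with 2.5% quantile at ",
              if (info == "beta_boundary_hi") p$low else p$high)
    else if (info == "uniform")
      message("PSA: parameter '", nm, "' admits no beta; sampled uniform on [",
              p$low, ", ", p$high, "]")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  strat_names <- vapply(strategies, function(s) s$name, "")
  par_mat <- matrix(NA_real_, n, length(sampled),
                    dimnames = list(NULL, sampled))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    b <- bundle
    for (nm in sampled) {
      v <- sample_parameter(b$params[[nm]])
      par_mat[i, nm] <- v
      b$params[[nm]]$base <- v
    }
    # keep the utility ordering invariant under sampling
    if (b$params$u_progressed$base > b$params$u_pfs$base)
      b$params$u_progressed$base <- b$params$u_pfs$base
    row <- lapply(strategies, evaluate_strategy, bundle = b)
    res[[i]] <- data.frame(draw = i, strategy = strat_names,
                           cost = vapply(row, `[[`, 0, "cost"),
                           qalys = vapply(row, `[[`, 0, "qalys"),
                           stringsAsFactors = FALSE)
  }
  structure(list(samples = do.call(rbind, c(res, list(make.row.names = FALSE))),
                 parameters = as.data.frame(par_mat),
                 wtp = bundle$run$wtp_per_qaly, seed = seed, n = n,
                 strategies = strat_names),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), strategies: %s\n", x$n, x$seed,
              paste(x$strategies, collapse = ", ")))
  ctrl <- x$strategies[1L]
  for (s in setdiff(x$strategies, ctrl))
    cat(sprintf("  P(%s cost-effective vs %s at WTP %g): %.3f\n", s, ctrl,
                x$wtp, ce_probability(x, s, ctrl, x$wtp)))
  invisible(x)
}

# probability that `test` has higher NMB than `comparator` at one WTP
ce_probability <- function(psa, test, comparator, wtp) {
  s <- psa$samples
  a <- s[s$strategy == test, ]
  b <- s[s$strategy == comparator, ]
  stopifnot(nrow(a) == nrow(b))
  mean((a$qalys * wtp - a$cost) > (b$qalys * wtp - b$cost))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the test strategy's net monetary benefit exceeds the comparator's.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty numeric vector of willingness-to-pay values.
#' @param test,comparator Strategy names as recorded in the PSA; defaults
#'   compare every non-control strategy against the first one.
#' @return A `cea_ceac` data frame: `wtp` and one probability column per
#'   test strategy, values in `[0, 1]`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2000),
                 test = setdiff(psa$strategies, comparator),
                 comparator = psa$strategies[1L]) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0) stop("WTP grid must be non-empty", call. = FALSE)
  out <- data.frame(wtp = wtp_grid)
  for (s in test)
    out[[paste0("prob_", gsub("[^[:alnum:]]+", "_", tolower(s)))]] <-
      vapply(wtp_grid, function(w) ce_probability(psa, s, comparator, w), 0)
  structure(out, class = c("cea_ceac", "data.frame"), comparator = comparator)
}

#' @export
plot.cea_ceac <- function(x, ...) {
  cols <- setdiff(names(x), "wtp")
  plot(NULL, xlim = range(x$wtp), ylim = c(0, 1),
       xlab = "willingness-to-pay (USD/QALY)",
       ylab = "P(cost-effective vs control)", ...)
  for (i in seq_along(cols)) lines(x$wtp, x[[cols[i]]], lty = i)
  legend("bottomright", legend = cols, lty = seq_along(cols), bty = "n")
  invisible(x)
}

#' Incremental scatter quadrant summary
#'
#' Classifies each PSA draw's incremental (QALY, cost) pair of a test
#' strategy versus the comparator into the four cost-effectiveness-plane
#' quadrants (NE: more effective & more costly, SE: more effective &
#' cheaper, SW: less effective & cheaper, NW: less effective & more
#' costly), and counts the draws below the willingness-to-pay line.
#'
#' @inheritParams ceac
#' @param test Single strategy name.
#' @param wtp Willingness-to-pay used for the acceptability count.
#' @return A list with `quadrants` (named counts summing to `n`) and
#'   `prob_cost_effective`.
#' @export
psa_quadrants <- function(psa, test, comparator = psa$strategies[1L],
                          wtp = psa$wtp) {
  s <- psa$samples
  a <- s[s$strategy == test, ]
  b <- s[s$strategy == comparator, ]
  de <- a$qalys - b$qalys
  dc <- a$cost - b$cost
  quad <- ifelse(de >= 0 & dc >= 0, "NE",
                 ifelse(de >= 0 & dc < 0, "SE",
                        ifelse(de < 0 & dc < 0, "SW", "NW")))
  counts <- table(factor(quad, levels = c("NE", "SE", "SW", "NW")))
  list(quadrants = stats::setNames(as.vector(counts), names(counts)),
       prob_cost_effective = mean(wtp * de - dc > 0))
}

#' One-way deterministic sensitivity analysis for one parameter
#'
#' Re-evaluates the ICER of a strategy pair with the named parameter at its
#' low and at its high bound, all other parameters at base.  The input
#' bundle is never modified.
#'
#' @param bundle A `cea_parameters` bundle.
#' @param parameter Parameter name (must have a range; see
#'   `names(bundle$params)`).
#' @param test,comparator [strategy_spec()] objects for the compared pair.
#' @return A `tornado_entry`: `parameter`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `span = |icer_at_high - icer_at_low|`.
#' @export
one_way <- function(bundle, parameter,
                    test = strategy_spec("ngs"),
                    comparator = strategy_spec("none")) {
  p <- bundle$params[[parameter]]
  if (is.null(p)) stop("unknown parameter '", parameter, "'; valid names: ",
                       paste(names(bundle$params), collapse = ", "),
                       call. = FALSE)
  icer_at <- function(value) {
    b <- param_set(bundle, parameter, value)
    icer(evaluate_strategy(test, b), evaluate_strategy(comparator, b))$icer
  }
  lo <- icer_at(p$low)
  hi <- icer_at(p$high)
  structure(list(parameter = parameter, low = p$low, high = p$high,
                 icer_at_low = lo, icer_at_high = hi,
                 span = abs(hi - lo)),
            class = "tornado_entry")
}

#' @export
print.tornado_entry <- function(x, ...) {
  cat(sprintf("%-28s ICER %0.0f @ %g  |  %0.0f @ %g  (span %0.0f)\n",
              x$parameter, x$icer_at_low, x$low, x$icer_at_high, x$high,
              x$span))
  invisible(x)
}

#' Tornado analysis over all ranged parameters
#'
#' Runs [one_way()] for every parameter with a non-degenerate range
#' (including the crizotinib half-price case and the discount rate) and
#' returns entries sorted by descending ICER span.
#'
#' @inheritParams one_way
#' @param parameters Character vector of parameter names; defaults to all
#'   parameters with `low < high`.
#' @return A `cea_tornado` data frame sorted by descending `span`.
#' @export
tornado <- function(bundle, test = strategy_spec("ngs"),
                    comparator = strategy_spec("none"),
                    parameters = NULL) {
  if (is.null(parameters))
    parameters <- names(bundle$params)[vapply(bundle$params,
                                              function(p) p$low < p$high, TRUE)]
  rows <- lapply(parameters, function(nm) {
    e <- one_way(bundle, nm, test, comparator)
    data.frame(parameter = e$parameter, low = e$low, high = e$high,
               icer_at_low = e$icer_at_low, icer_at_high = e$icer_at_high,
               span = e$span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, class = c("cea_tornado", "data.frame"))
}

#' @export
plot.cea_tornado <- function(x, n = min(nrow(x), 12), base_icer = NULL, ...) {
  d <- x[n:1, ]
  mid <- if (is.null(base_icer)) mean(c(d$icer_at_low, d$icer_at_high)) else base_icer
  rng <- range(c(d$icer_at_low, d$icer_at_high))
  old <- par(mar = c(4, 12, 2, 1)); on.exit(par(old))
  plot(NULL, xlim = rng, ylim = c(0.5, n + 0.5), yaxt = "n",
       xlab = "ICER (USD/QALY)", ylab = "", ...)
  for (i in seq_len(n)) {
    segments(pmin(d$icer_at_low[i], d$icer_at_high[i]), i,
             pmax(d$icer_at_low[i], d$icer_at_high[i]), i, lwd = 8,
             col = "grey60")
  }
  abline(v = mid, lty = 2)
  axis(2, at = seq_len(n), labels = d$parameter, las = 1, cex.axis = 0.7)
  invisible(x)
}
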