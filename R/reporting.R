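# Report generation: CSV outputs mirroring the published tables/figures,
# each accompanied by a JSON run manifest for auditability.

write_manifest <- function(out_dir, bundle, extra = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(bundle, tmp)
  manifest <- c(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "alkcea",
    version = as.character(utils::packageVersion("alkcea")),
    config_md5 = unname(tools::md5sum(tmp)),
    conventions = list(
      cycle_days = bundle$run$cycle_days,
      chemo_time_unit = bundle$run$chemo_time_unit,
      criz_time_unit = bundle$run$criz_time_unit,
      salvage_max_cycles = bundle$run$salvage_max_cycles,
      pap = bundle$run$pap,
      test_cost_policy = bundle$run$test_cost_policy,
      half_cycle_correction = bundle$run$half_cycle_correction
    )
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Base-case report
#'
#' Evaluates the strategies and writes `base_case.csv` (columns `strategy`,
#' `cost`, `pf_ly`, `overall_ly`, `qalys`, `icer_vs_control`, `nmb_at_wtp`,
#' mirroring the published base-case table layout) plus `manifest.json` to
#' `out_dir`.
#'
#' @param bundle A `cea_parameters` bundle (or a config path; strings are
#'   passed through [load_config()]).
#' @param strategies List of [strategy_spec()].
#' @param out_dir Output directory, created if needed.
#' @return The [run_cea()] result, invisibly.
#' @export
report_base_case <- function(bundle = default_parameters(),
                             strategies = list(strategy_spec("none"),
                                               strategy_spec("ngs"),
                                               strategy_spec("pcr")),
                             out_dir = ".") {
  if (is.character(bundle)) bundle <- load_config(bundle)
  res <- run_cea(bundle, strategies)        # fail before touching out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary(res), file.path(out_dir, "base_case.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, bundle, list(report = "base_case"))
  invisible(res)
}

#' One-way sensitivity (tornado) report
#'
#' Writes `tornado.csv` (columns `parameter`, `low`, `high`,
#' `icer_at_low`, `icer_at_high`, `span`, sorted by descending span) plus
#' `manifest.json`.
#'
#' @inheritParams report_base_case
#' @param test,comparator The compared pair, as [strategy_spec()] objects.
#' @return The [tornado()] data frame, invisibly.
#' @export
report_dsa <- function(bundle = default_parameters(),
                       test = strategy_spec("ngs"),
                       comparator = strategy_spec("none"),
                       out_dir = ".") {
  if (is.character(bundle)) bundle <- load_config(bundle)
  tor <- tornado(bundle, test, comparator)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(tor), file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, bundle,
                 list(report = "dsa", test = test$name,
                      comparator = comparator$name))
  invisible(tor)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs the PSA and writes `psa_samples.csv` (`draw,strategy,cost,qalys`),
#' `psa_parameters.csv` (sampled parameter values per draw), `ceac.csv`
#' (`wtp` plus one acceptability column per test strategy), a quadrant
#' summary `psa_summary.csv` with the proportion cost-effective at the
#' configured willingness-to-pay, and `manifest.json`.
#'
#' @inheritParams report_base_case
#' @param n Number of simulations.
#' @param seed RNG seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return The [run_psa()] result, invisibly.
#' @export
report_psa <- function(bundle = default_parameters(),
                       strategies = list(strategy_spec("none"),
                                         strategy_spec("ngs"),
                                         strategy_spec("pcr")),
                       n = 1000, seed = 20161023,
                       wtp_grid = seq(0, 100000, by = 2000),
                       out_dir = ".") {
  if (is.character(bundle)) bundle <- load_config(bundle)
  psa <- run_psa(bundle, strategies, n = n, seed = seed)
  cc <- ceac(psa, wtp_grid)
  ctrl <- psa$strategies[1L]
  summ <- do.call(rbind, lapply(setdiff(psa$strategies, ctrl), function(s) {
    q <- psa_quadrants(psa, s)
    data.frame(strategy = s, wtp = psa$wtp,
               prob_cost_effective = q$prob_cost_effective,
               ne = q$quadrants[["NE"]], se = q$quadrants[["SE"]],
               sw = q$quadrants[["SW"]], nw = q$quadrants[["NW"]])
  }))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(psa$samples, file.path(out_dir, "psa_samples.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(draw = seq_len(psa$n), psa$parameters),
                   file.path(out_dir, "psa_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cc), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  utils::write.csv(summ, file.path(out_dir, "psa_summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, bundle, list(report = "psa", n = n, seed = seed))
  invisible(psa)
}
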