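# Reporting layer: runs strategies from a model configuration and produces
# the base-case cost-effectiveness table with frontier labels, plus run
# manifests and result writers.

#' Run one strategy from a model configuration
#'
#' Derives the three transition schedules (recurrence from the strategy's
#' schedule, post-recurrence mortality from the strategy's stratum,
#' background mortality from the life table), runs the cohort engine and
#' computes costs, DALYs and overall survival.
#'
#' @param config A [make_full_config()] configuration.
#' @param key Strategy key in `config$strategies`.
#'
#' @return List with `trace`, `cost` (see [discounted_costs()]), `dalys`
#'   and `os_years`.
#' @export
run_strategy <- function(config, key) {
  strat <- config$strategies[[key]]
  if (is.null(strat)) stop(sprintf("unknown strategy '%s'", key))
  h <- config$settings$horizon
  sched <- transition_schedules(
    p_recur = strat$p_recur,
    p_death_cc = config$post_recurrence[[strat$pr_stratum]],
    p_death_other = life_table_to_monthly(config$life_table,
                                          config$settings$start_age, h)
  )
  trace <- run_cohort(config$settings, strat, sched, config$pathway)
  cost <- discounted_costs(trace, strat, config$costs, config$econ)
  dalys <- compute_dalys(trace, strat, config$weights, config$econ)
  list(trace = trace, cost = cost, dalys = dalys,
       os_years = overall_survival_years(trace))
}

#' Base-case cost-effectiveness analysis
#'
#' Runs every strategy in the configuration, computes DALYs averted against
#' the comparator and classifies the strategies on the cost-effectiveness
#' frontier at the configured willingness-to-pay.
#'
#' @param config A [make_full_config()] configuration.
#'
#' @return A `cea_frontier` tibble with one row per strategy: costs in both
#'   currencies, undiscounted overall survival, discounted YLL/YLD/DALYs,
#'   DALYs averted, sequential ICER, NMB, dominance label and the
#'   recommended flag.
#' @export
run_base_case <- function(config) {
  keys <- names(config$strategies)
  runs <- lapply(keys, function(k) run_strategy(config, k))
  names(runs) <- keys
  comp <- config$econ$comparator
  if (!comp %in% keys) stop(sprintf("comparator '%s' is not a strategy", comp))
  col <- function(f) unname(vapply(runs, f, numeric(1L)))
  tab <- tibble::tibble(
    strategy = keys,
    label = unname(vapply(config$strategies, function(s) s$name, character(1L))),
    cost = col(function(r) r$cost$total_int),
    cost_zar = col(function(r) r$cost$total_zar),
    os_years = col(function(r) r$os_years),
    yll = col(function(r) r$dalys$yll),
    yld = col(function(r) r$dalys$yld),
    daly = col(function(r) r$dalys$daly)
  )
  tab$dalys_averted <- tab$daly[tab$strategy == comp] - tab$daly
  frontier(tab, wtp = config$econ$wtp)
}

#' Recommended strategy of a frontier table
#'
#' @param cea A `cea_frontier` tibble.
#' @return The strategy key flagged as recommended.
#' @export
recommended_strategy <- function(cea) {
  cea$strategy[cea$recommended][1L]
}

#' Run manifest
#'
#' Reproducibility metadata attached to written outputs: configuration
#' hash, seed, package version, timestamp and output file list.
#'
#' @param config The configuration used.
#' @param seed Seed used for any stochastic component (or `NA`).
#' @param files Character vector of output files.
#' @return A list; write it with [jsonlite::write_json()].
#' @export
run_manifest <- function(config, seed = NA_integer_, files = character(0)) {
  list(
    config_hash = rlang::hash(config),
    stage = config$stage,
    seed = seed,
    package_version = as.character(utils::packageVersion("coloncea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files)
  )
}

#' Write a cost-effectiveness table (and manifest) to disk
#'
#' Emits `<name>.csv` and `<name>.json` mirroring the base-case table
#' columns, plus `<name>_manifest.json`.
#'
#' @param cea A `cea_frontier` tibble.
#' @param config The configuration it came from.
#' @param dir Output directory (created if needed).
#' @param name File stem, default `"base_case"`.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the files written.
#' @export
write_cea_results <- function(cea, config, dir, name = "base_case",
                              seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, ".json"))
  mf <- file.path(dir, paste0(name, "_manifest.json"))
  utils::write.csv(tibble::as_tibble(cea), csv, row.names = FALSE)
  jsonlite::write_json(tibble::as_tibble(cea), js, digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(run_manifest(config, seed, files = c(csv, js)), mf,
                       auto_unbox = TRUE)
  invisible(c(csv, js, mf))
}
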