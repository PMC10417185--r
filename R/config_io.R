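# Configuration serialisation: a model configuration is materialised as one
# YAML file plus plain CSV tables (schedules, curves, life table, costs,
# weights, surveillance calendar), the same dialects the loaders read.

#' Write a model configuration to a fixture directory
#'
#' Materialises a complete runnable fixture directory: `config.yaml` with
#' the scalar parameters, per-strategy recurrence schedules and DFS curves,
#' the post-recurrence survival curves, the life table, the cost, weight
#' and surveillance tables. Writing is deterministic: the same
#' configuration always produces byte-identical files.
#'
#' @param config A [make_full_config()] configuration.
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_config_dir <- function(config, dir) {
  dir.create(file.path(dir, "schedules"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "curves"), showWarnings = FALSE)

  strat_meta <- lapply(config$strategies, function(s) {
    list(key = s$key, name = s$name,
         adjuvant_duration = s$adjuvant_duration,
         adjuvant_cost_zar = s$adjuvant_cost_zar,
         first_line = s$first_line, second_line = s$second_line,
         pr_stratum = s$pr_stratum,
         ae_incidence = as.list(s$ae_incidence),
         residual_neuropathy_incidence = s$residual_neuropathy_incidence)
  })
  yaml::write_yaml(
    list(stage = config$stage, seed = config$seed,
         subgroup = config$subgroup,
         settings = list(start_age = config$settings$start_age,
                         max_age = config$settings$max_age,
                         annual_discount_rate = config$settings$annual_discount_rate),
         econ = unclass(config$econ),
         pathway = unclass(config$pathway),
         regimen_costs_zar = as.list(config$regimen_costs_zar),
         weights = list(recurrence = config$weights$recurrence,
                        cc_death = config$weights$cc_death,
                        ae = as.list(config$weights$ae)),
         weight_ranges = config$weight_ranges,
         strategies = strat_meta),
    file.path(dir, "config.yaml")
  )

  for (s in config$strategies) {
    write_schedule(s$p_recur,
                   file.path(dir, "schedules", paste0("recurrence_", s$key, ".csv")))
    write_survival_curve(s$dfs_curve,
                         file.path(dir, "curves", paste0("dfs_", s$key, ".csv")))
  }
  for (st in names(config$post_recurrence_curves)) {
    write_survival_curve(config$post_recurrence_curves[[st]],
                         file.path(dir, "curves",
                                   paste0("post_recurrence_", st, ".csv")))
  }
  write_life_table(config$life_table, file.path(dir, "life_table.csv"))
  utils::write.csv(
    data.frame(item = names(config$costs$shared),
               zar = unname(config$costs$shared)),
    file.path(dir, "costs.csv"), row.names = FALSE, quote = FALSE
  )
  utils::write.csv(config$costs$surveillance,
                   file.path(dir, "surveillance.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a model configuration from a fixture directory
#'
#' Reads back what [write_config_dir()] wrote, validating every table on
#' load and reporting the offending file on failure.
#'
#' @param dir Directory written by [write_config_dir()].
#' @return A `model_config`.
#' @export
read_config_dir <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "config.yaml"))
  settings <- model_settings(start_age = y$settings$start_age,
                             max_age = y$settings$max_age,
                             annual_discount_rate = y$settings$annual_discount_rate)
  econ <- econ_settings(wtp = y$econ$wtp, ppp_factor = y$econ$ppp_factor,
                        annual_discount_rate = y$econ$annual_discount_rate,
                        comparator = y$econ$comparator)
  pathway <- recurrence_pathway(y$pathway$frac_liver_only,
                                y$pathway$frac_hepatectomy_given_liver_only)

  strategies <- lapply(y$strategies, function(m) {
    key <- m$key
    strategy_spec(
      key = key, name = m$name, adjuvant_duration = m$adjuvant_duration,
      adjuvant_cost_zar = m$adjuvant_cost_zar,
      first_line = m$first_line, second_line = m$second_line,
      pr_stratum = m$pr_stratum,
      ae_incidence = unlist(m$ae_incidence),
      residual_neuropathy_incidence = m$residual_neuropathy_incidence,
      p_recur = read_schedule(file.path(dir, "schedules",
                                        paste0("recurrence_", key, ".csv"))),
      dfs_curve = read_survival_curve(file.path(dir, "curves",
                                                paste0("dfs_", key, ".csv")),
                                      label = paste(y$stage, key, "DFS"))
    )
  })
  names(strategies) <- vapply(strategies, function(s) s$key, character(1L))

  pr_curves <- list(
    doublet = read_survival_curve(
      file.path(dir, "curves", "post_recurrence_doublet.csv"),
      label = "post-recurrence, doublet"),
    single_or_none = read_survival_curve(
      file.path(dir, "curves", "post_recurrence_single_or_none.csv"),
      label = "post-recurrence, single agent or none")
  )
  costs <- utils::read.csv(file.path(dir, "costs.csv"))

  structure(
    list(stage = y$stage, seed = y$seed, settings = settings, econ = econ,
         pathway = pathway, strategies = strategies,
         post_recurrence = lapply(pr_curves, curve_to_monthly_probs),
         post_recurrence_curves = pr_curves,
         life_table = read_life_table(file.path(dir, "life_table.csv")),
         weights = disability_weights(recurrence = y$weights$recurrence,
                                      cc_death = y$weights$cc_death,
                                      ae = unlist(y$weights$ae)),
         weight_ranges = lapply(y$weight_ranges, unlist),
         regimen_costs_zar = unlist(y$regimen_costs_zar),
         costs = list(shared = stats::setNames(costs$zar, costs$item),
                      surveillance = utils::read.csv(
                        file.path(dir, "surveillance.csv"))),
         subgroup = y$subgroup),
    class = "model_config"
  )
}
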