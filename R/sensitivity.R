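# Sensitivity analyses: one-way deterministic sweeps with tornado output
# and threshold search, probabilistic sensitivity analysis with beta/gamma/
# PERT draws and cost-effectiveness acceptability curves, and the subgroup
# and scenario re-parameterisations.

#' Probabilistic distribution specification for one parameter
#'
#' Families follow the conventions of the sensitivity design: BETA for
#' probabilities and weights (method-of-moments from mean = base and
#' sd = `sd_fraction` x base, base case 10 percent), GAMMA for non-negative
#' costs (method-of-moments, base case 25 percent), classical PERT with
#' shape 4 for the disability weights (mode = base over `[min, max]`), and
#' FIXED for degenerate draws.
#'
#' @param parameter Parameter path understood by [perturb_config()].
#' @param family `"BETA"`, `"GAMMA"`, `"PERT"` or `"FIXED"`.
#' @param base Base-case value (the mean for BETA/GAMMA, the mode for PERT).
#' @param sd_fraction Standard deviation as a fraction of base (BETA/GAMMA).
#' @param min,max PERT bounds.
#' @param strategy Optional strategy key restricting the parameter's scope.
#' @param mode `"multiplier"` (sampled value divided by base scales the
#'   target) or `"absolute"`.
#'
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(parameter, family = c("BETA", "GAMMA", "PERT", "FIXED"),
                      base, sd_fraction = NULL, min = NULL, max = NULL,
                      strategy = NULL, mode = c("multiplier", "absolute")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (family == "BETA") {
    if (base < 0 || base > 1) stop("BETA requires a base value in [0, 1]")
    sd <- sd_fraction * base
    if (sd^2 >= base * (1 - base)) {
      stop(sprintf("BETA moment matching infeasible for '%s': sd %.4g too large for mean %.4g",
                   parameter, sd, base))
    }
  }
  if (family == "GAMMA" && base < 0) stop("GAMMA requires a non-negative base")
  if (family == "PERT") {
    if (is.null(min) || is.null(max) || min > base || base > max) {
      stop(sprintf("PERT for '%s' requires min <= base <= max", parameter))
    }
  }
  structure(list(parameter = parameter, family = family, base = base,
                 sd_fraction = sd_fraction, min = min, max = max,
                 strategy = strategy, mode = mode),
            class = "dist_spec")
}

#' Sample from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_parameter <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    FIXED = rep(spec$base, n),
    BETA = {
      mu <- spec$base
      sd <- spec$sd_fraction * mu
      nu <- mu * (1 - mu) / sd^2 - 1
      stats::rbeta(n, mu * nu, (1 - mu) * nu)
    },
    GAMMA = {
      if (spec$base == 0) return(rep(0, n))
      shape <- 1 / spec$sd_fraction^2
      stats::rgamma(n, shape = shape, rate = shape / spec$base)
    },
    PERT = {
      a <- spec$min
      b <- spec$max
      m <- spec$base
      if (b - a < 1e-12) return(rep(m, n))
      al <- 1 + 4 * (m - a) / (b - a)
      be <- 1 + 4 * (b - m) / (b - a)
      a + (b - a) * stats::rbeta(n, al, be)
    }
  )
}

# ---- parameter perturbation -----------------------------------------------

#' Perturb one model parameter
#'
#' The common dispatcher behind the deterministic and probabilistic
#' sensitivity analyses. Time-varying schedules are perturbed by a single
#' hazard-scale multiplier (via [apply_hazard_ratio()]) so curves stay
#' coherent; costs are scaled multiplicatively; weights and the discount
#' rate are set absolutely.
#'
#' Supported parameter paths: `discount_rate`, `wtp` (absolute);
#' `p_recurrence`, `p_death_cc`, `p_death_other`, `ae_incidence`
#' (multiplier); `cost_adjuvant`, `cost_first_line`, `cost_second_line`
#' (multiplier, optionally per strategy); `weight_recurrence` and
#' `weight_<event>` (absolute).
#'
#' @param config A model configuration.
#' @param parameter Parameter path.
#' @param value Multiplier or absolute value depending on the path.
#' @param strategy Optional strategy key restricting cost perturbations.
#' @return The perturbed configuration.
#' @export
perturb_config <- function(config, parameter, value, strategy = NULL) {
  keys <- if (is.null(strategy)) names(config$strategies) else strategy
  if (!all(keys %in% names(config$strategies))) {
    stop(sprintf("unknown strategy '%s'", setdiff(keys, names(config$strategies))[1L]))
  }
  if (parameter == "discount_rate") {
    config$settings$annual_discount_rate <- value
    config$econ$annual_discount_rate <- value
  } else if (parameter == "wtp") {
    config$econ$wtp <- value
  } else if (parameter == "p_recurrence") {
    for (k in keys) {
      config$strategies[[k]]$p_recur <-
        apply_hazard_ratio(config$strategies[[k]]$p_recur, value)
    }
  } else if (parameter == "p_death_cc") {
    config$post_recurrence <- lapply(config$post_recurrence,
                                     apply_hazard_ratio, hazard_ratio = value)
  } else if (parameter == "p_death_other") {
    config$life_table$annual_death_prob <-
      apply_hazard_ratio(config$life_table$annual_death_prob, value)
  } else if (parameter == "ae_incidence") {
    for (k in keys) {
      s <- config$strategies[[k]]
      s$ae_incidence <- pmin(s$ae_incidence * value, 1)
      s$residual_neuropathy_incidence <-
        min(s$residual_neuropathy_incidence * value, 1)
      config$strategies[[k]] <- s
    }
  } else if (parameter == "cost_adjuvant") {
    for (k in keys) {
      config$strategies[[k]]$adjuvant_cost_zar <-
        config$strategies[[k]]$adjuvant_cost_zar * value
    }
  } else if (parameter == "cost_first_line") {
    for (k in keys) {
      config$strategies[[k]]$first_line$cost_zar <-
        config$strategies[[k]]$first_line$cost_zar * value
    }
  } else if (parameter == "cost_second_line") {
    for (k in keys) {
      config$strategies[[k]]$second_line$cost_zar <-
        config$strategies[[k]]$second_line$cost_zar * value
    }
  } else if (parameter == "weight_recurrence") {
    config$weights$recurrence <- value
  } else if (grepl("^weight_", parameter)) {
    ev <- sub("^weight_", "", parameter)
    if (!ev %in% names(config$weights$ae)) {
      stop(sprintf("cannot resolve parameter path '%s'", parameter))
    }
    config$weights$ae[[ev]] <- value
  } else {
    stop(sprintf("cannot resolve parameter path '%s'", parameter))
  }
  config
}

# ICER of comparison[1] versus comparison[2] on a configuration.
.icer_pair <- function(config, comparison) {
  a <- run_strategy(config, comparison[1L])
  b <- run_strategy(config, comparison[2L])
  (a$cost$total_int - b$cost$total_int) / (b$dalys$daly - a$dalys$daly)
}

#' One-way deterministic sensitivity analysis for one parameter
#'
#' Re-runs both comparison strategies deterministically with the parameter
#' at its low and high bound and reports the resulting pairwise ICERs.
#'
#' @param config A model configuration.
#' @param parameter Parameter path (see [perturb_config()]).
#' @param low,high Bounds (multipliers or absolute values per the path).
#' @param comparison Character pair `c(intervention, comparator)`.
#' @param strategy Optional strategy scope for cost parameters.
#'
#' @return Tibble with `parameter`, `icer_low`, `icer_high`, `spread`.
#' @export
one_way_dsa <- function(config, parameter, low, high, comparison,
                        strategy = NULL) {
  stopifnot(low <= high, length(comparison) == 2L)
  lo <- .icer_pair(perturb_config(config, parameter, low, strategy), comparison)
  hi <- .icer_pair(perturb_config(config, parameter, high, strategy), comparison)
  tibble::tibble(
    parameter = if (is.null(strategy)) parameter else paste(parameter, strategy, sep = ":"),
    low = low, high = high, icer_low = lo, icer_high = hi,
    spread = abs(hi - lo)
  )
}

#' Default tornado parameter set
#'
#' Deterministic ranges: probabilities varied -25/+25 percent (hazard-scale
#' multipliers 0.75 and 1.25), costs -50/+100 percent, the discount rate
#' over 0-0.10 absolutely, and the recurrence disability weight over its
#' PERT bounds. Adjuvant drug cost is varied separately for each comparison
#' arm.
#'
#' @param config A model configuration.
#' @param comparison Character pair `c(intervention, comparator)`.
#' @return Data frame of tornado specifications.
#' @export
default_tornado_specs <- function(config, comparison) {
  rw <- config$weight_ranges$recurrence
  rbind(
    data.frame(parameter = "p_recurrence", low = 0.75, high = 1.25,
               strategy = NA_character_),
    data.frame(parameter = "p_death_cc", low = 0.75, high = 1.25,
               strategy = NA_character_),
    data.frame(parameter = "ae_incidence", low = 0.75, high = 1.25,
               strategy = NA_character_),
    data.frame(parameter = "cost_adjuvant", low = 0.5, high = 2,
               strategy = comparison),
    data.frame(parameter = "cost_first_line", low = 0.5, high = 2,
               strategy = NA_character_),
    data.frame(parameter = "discount_rate", low = 0, high = 0.10,
               strategy = NA_character_),
    data.frame(parameter = "weight_recurrence", low = rw[1L], high = rw[2L],
               strategy = NA_character_)
  )
}

#' Tornado analysis
#'
#' Runs [one_way_dsa()] for every specification and sorts parameters by the
#' width of their ICER interval.
#'
#' @inheritParams default_tornado_specs
#' @param specs Tornado specifications (default [default_tornado_specs()]).
#' @return Tibble sorted by descending `spread`, with the base-case ICER
#'   attached as an attribute.
#' @export
run_tornado <- function(config, comparison, specs = NULL) {
  if (is.null(specs)) specs <- default_tornado_specs(config, comparison)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs$strategy[i]
    one_way_dsa(config, specs$parameter[i], specs$low[i], specs$high[i],
                comparison, strategy = if (is.na(s)) NULL else s)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  attr(out, "icer_base") <- .icer_pair(config, comparison)
  attr(out, "comparison") <- comparison
  out
}

#' Threshold multiplier at which a pairwise ICER crosses the WTP
#'
#' Bisection (via [stats::uniroot()]) for the multiplier of a parameter's
#' base value at which the ICER of `comparison[1]` versus `comparison[2]`
#' equals `wtp`, to a relative tolerance of `1e-4`. When the ICER does not
#' cross `wtp` inside the interval the result reports "no threshold"
#' rather than raising an error.
#'
#' @inheritParams one_way_dsa
#' @param wtp Willingness-to-pay threshold (I$ per DALY averted).
#' @param interval Multiplier search interval.
#' @param tol Relative tolerance of the root.
#' @return List with `multiplier` (`NA` when there is no crossing),
#'   `status`, and the ICERs at the interval ends.
#' @export
threshold_multiplier <- function(config, parameter, comparison, wtp,
                                 interval = c(0.25, 2.5), tol = 1e-4,
                                 strategy = NULL) {
  f <- function(m) {
    .icer_pair(perturb_config(config, parameter, m, strategy), comparison) - wtp
  }
  f_lo <- f(interval[1L])
  f_hi <- f(interval[2L])
  if (sign(f_lo) == sign(f_hi)) {
    return(list(multiplier = NA_real_, status = "no threshold",
                icer_low = f_lo + wtp, icer_high = f_hi + wtp))
  }
  root <- stats::uniroot(f, interval, tol = tol * mean(interval))
  list(multiplier = root$root, status = "ok",
       icer_low = f_lo + wtp, icer_high = f_hi + wtp)
}

# ---- probabilistic sensitivity analysis -----------------------------------

#' Default PSA distribution set for a configuration
#'
#' Probabilities (recurrence, post-recurrence mortality, background
#' mortality, adverse-event incidence) draw a BETA-distributed reference
#' probability with sd 10 percent of base and apply the draw/base ratio as
#' a hazard-scale multiplier shared across arms; course costs draw GAMMA
#' multipliers with sd 25 percent shared per cost item; disability weights
#' draw absolute PERT values over their published ranges. The
#' willingness-to-pay and the discount rate are excluded (handled by the
#' WTP grid and the deterministic analysis).
#'
#' @param config A model configuration.
#' @return Named list of [dist_spec()]s.
#' @export
psa_distributions <- function(config) {
  ref_recur <- mean(config$strategies[[config$econ$comparator]]$p_recur)
  ref_dcc <- mean(config$post_recurrence$doublet[1:60])
  ref_do <- 1 - (1 - config$life_table$annual_death_prob[
    findInterval(config$settings$start_age, config$life_table$age_lower)])^(1 / 12)
  specs <- list(
    p_recurrence = dist_spec("p_recurrence", "BETA", ref_recur, sd_fraction = 0.10),
    p_death_cc = dist_spec("p_death_cc", "BETA", ref_dcc, sd_fraction = 0.10),
    p_death_other = dist_spec("p_death_other", "BETA", ref_do, sd_fraction = 0.10),
    ae_incidence = dist_spec("ae_incidence", "BETA", 0.05, sd_fraction = 0.10),
    cost_adjuvant = dist_spec("cost_adjuvant", "GAMMA", 1, sd_fraction = 0.25),
    cost_first_line = dist_spec("cost_first_line", "GAMMA", 1, sd_fraction = 0.25),
    cost_second_line = dist_spec("cost_second_line", "GAMMA", 1, sd_fraction = 0.25),
    weight_recurrence = dist_spec("weight_recurrence", "PERT",
                                  config$weights$recurrence,
                                  min = config$weight_ranges$recurrence[1L],
                                  max = config$weight_ranges$recurrence[2L],
                                  mode = "absolute")
  )
  for (ev in names(config$weights$ae)) {
    rng <- config$weight_ranges[[ev]]
    specs[[paste0("weight_", ev)]] <-
      dist_spec(paste0("weight_", ev), "PERT", config$weights$ae[[ev]],
                min = rng[1L], max = rng[2L], mode = "absolute")
  }
  specs
}

#' Probabilistic sensitivity analysis
#'
#' For each iteration one joint draw of all parameters is applied to every
#' strategy (parameters are common across arms), the model is run
#' deterministically, and the NMB-maximal strategy is recorded at every
#' willingness-to-pay grid point. Iterations producing invalid
#' probabilities are rejected and counted. Results are reproducible under a
#' fixed seed.
#'
#' @param config A model configuration.
#' @param n_iterations Number of PSA iterations (published analysis:
#'   100,000; desk default 5,000).
#' @param seed RNG seed.
#' @param wtp_grid Willingness-to-pay grid; defaults to one-half to three
#'   times the configured WTP in quarter steps.
#' @param distributions Named list of [dist_spec()]s
#'   (default [psa_distributions()]).
#'
#' @return A `psa_result` list: `draws` (per-iteration strategy, cost I$,
#'   DALYs, DALYs averted), `ceac` (probability each strategy is optimal at
#'   each WTP), `optimal_base` (optimal-strategy frequency at the
#'   configured WTP), `parameters` (the sampled values), `n_iterations`,
#'   `n_rejected`, `seed` and the configuration hash.
#' @export
run_psa <- function(config, n_iterations = 1000L, seed = 1L,
                    wtp_grid = NULL, distributions = NULL) {
  stopifnot(n_iterations >= 1L)
  if (is.null(wtp_grid)) {
    wtp_grid <- config$econ$wtp * seq(0.5, 3, by = 0.25)
  }
  wtp_grid <- sort(wtp_grid)
  if (is.null(distributions)) distributions <- psa_distributions(config)
  set.seed(seed)
  keys <- names(config$strategies)
  comp <- config$econ$comparator
  n_par <- length(distributions)
  par_mat <- matrix(NA_real_, n_iterations, n_par,
                    dimnames = list(NULL, names(distributions)))
  cost_mat <- matrix(NA_real_, n_iterations, length(keys),
                     dimnames = list(NULL, keys))
  daly_mat <- cost_mat
  rejected <- 0L
  for (it in seq_len(n_iterations)) {
    draws <- vapply(distributions, sample_parameter, numeric(1L))
    cfg <- config
    ok <- TRUE
    for (j in seq_along(distributions)) {
      sp <- distributions[[j]]
      val <- if (sp$mode == "multiplier") draws[j] / sp$base else draws[j]
      cfg <- tryCatch(perturb_config(cfg, sp$parameter, val, sp$strategy),
                      error = function(e) {
                        ok <<- FALSE
                        cfg
                      })
      if (!ok) break
    }
    if (!ok) {
      rejected <- rejected + 1L
      next
    }
    par_mat[it, ] <- draws
    for (k in keys) {
      r <- run_strategy(cfg, k)
      cost_mat[it, k] <- r$cost$total_int
      daly_mat[it, k] <- r$dalys$daly
    }
  }
  done <- which(!is.na(cost_mat[, 1L]))
  averted <- daly_mat[done, comp] - daly_mat[done, , drop = FALSE]
  draws_tbl <- tibble::tibble(
    iteration = rep(done, times = length(keys)),
    strategy = rep(keys, each = length(done)),
    cost = as.vector(cost_mat[done, , drop = FALSE]),
    daly = as.vector(daly_mat[done, , drop = FALSE]),
    dalys_averted = as.vector(averted)
  )
  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    nmb <- w * averted - cost_mat[done, , drop = FALSE]
    best <- keys[max.col(nmb, ties.method = "first")]
    data.frame(wtp = w, strategy = keys,
               probability_optimal = as.vector(table(factor(best, levels = keys))) /
                 length(done))
  }))
  nmb0 <- config$econ$wtp * averted - cost_mat[done, , drop = FALSE]
  best0 <- keys[max.col(nmb0, ties.method = "first")]
  optimal_base <- tibble::tibble(
    strategy = keys,
    probability_optimal = as.vector(table(factor(best0, levels = keys))) /
      length(done)
  )
  structure(
    list(draws = draws_tbl, ceac = tibble::as_tibble(ceac),
         optimal_base = optimal_base, parameters = par_mat[done, , drop = FALSE],
         n_iterations = n_iterations, n_rejected = rejected, seed = seed,
         wtp_grid = wtp_grid, config_hash = rlang::hash(config)),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (%d rejected), seed %s\n",
              x$n_iterations, x$n_rejected, format(x$seed)))
  best <- x$optimal_base[order(-x$optimal_base$probability_optimal), ]
  cat(sprintf("optimal at base WTP: %s (%.1f%% of iterations)\n",
              best$strategy[1L], 100 * best$probability_optimal[1L]))
  invisible(x)
}

# ---- subgroup and scenario ------------------------------------------------

#' Default subgroup recurrence-hazard multipliers
#'
#' Synthetic stand-ins for the unpublished subgroup-specific recurrence
#' inputs, chosen on clinical grounds: high-recurrence-risk subgroups carry
#' elevated hazards with a relatively larger benefit of 6 months of doublet
#' therapy (the duration-by-risk interaction reported by the adjuvant
#' duration trials); low-risk subgroups scale all arms down equally.
#'
#' @param stage `"HIGH_RISK_II"` or `"III"`.
#' @return Named list of named per-strategy multiplier vectors.
#' @export
subgroup_multipliers <- function(stage = c("HIGH_RISK_II", "III")) {
  stage <- match.arg(stage)
  if (stage == "HIGH_RISK_II") {
    list(
      T4 = c(no_adjuvant = 1.9, cape6 = 1.8, capox3 = 1.8, capox6 = 1.45),
      T3 = c(no_adjuvant = 0.85, cape6 = 0.85, capox3 = 0.85, capox6 = 0.85),
      LN_LT10 = c(no_adjuvant = 1.15, cape6 = 1.15, capox3 = 1.15, capox6 = 1.15),
      LN_GE10 = c(no_adjuvant = 0.9, cape6 = 0.9, capox3 = 0.9, capox6 = 0.9)
    )
  } else {
    list(
      T4_or_N2 = c(no_adjuvant = 1.75, cape6 = 1.70, capox3 = 1.65, capox6 = 1.30),
      T3N1 = c(no_adjuvant = 0.75, cape6 = 0.75, capox3 = 0.75, capox6 = 0.75)
    )
  }
}

#' Subgroup re-parameterisation
#'
#' Returns a configuration whose recurrence schedules are hazard-scaled by
#' per-strategy multipliers (via [apply_hazard_ratio()] semantics); all
#' other inputs are unchanged. Supply real subgroup-derived multipliers via
#' `multipliers` to replace the shipped stand-ins.
#'
#' @param config A model configuration.
#' @param subgroup Label of a shipped subgroup (see
#'   [subgroup_multipliers()]); ignored when `multipliers` is given.
#' @param multipliers Positive scalar or named per-strategy vector of
#'   hazard multipliers.
#' @return The re-parameterised configuration (with `$subgroup` set).
#' @export
subgroup_model <- function(config, subgroup = NULL, multipliers = NULL) {
  if (is.null(multipliers)) {
    if (is.null(subgroup)) stop("give either `subgroup` or `multipliers`")
    multipliers <- subgroup_multipliers(config$stage)[[subgroup]]
    if (is.null(multipliers)) stop(sprintf("unknown subgroup '%s'", subgroup))
  }
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  keys <- names(config$strategies)
  m <- if (length(multipliers) == 1L && is.null(names(multipliers))) {
    stats::setNames(rep(multipliers, length(keys)), keys)
  } else {
    if (!all(keys %in% names(multipliers))) {
      stop("named multipliers must cover every strategy")
    }
    multipliers[keys]
  }
  for (k in keys) {
    config$strategies[[k]]$p_recur <-
      apply_hazard_ratio(config$strategies[[k]]$p_recur, m[[k]])
  }
  config$subgroup <- subgroup %||% "custom"
  config
}

#' Capecitabine-only metastatic scenario
#'
#' Replaces every FOLFIRI metastatic line with XELIRI: the line's course
#' cost switches to the XELIRI cost while the survival schedules are left
#' unchanged (the two regimens are treated as equivalent in effectiveness).
#' A configuration without any FOLFIRI line is returned unchanged.
#'
#' @param config A model configuration with `regimen_costs_zar` containing
#'   an `XELIRI` entry.
#' @return The re-parameterised configuration.
#' @export
scenario_xeliri <- function(config) {
  if (!"XELIRI" %in% names(config$regimen_costs_zar)) {
    stop("missing XELIRI cost row in `regimen_costs_zar`")
  }
  xe <- unname(config$regimen_costs_zar[["XELIRI"]])
  for (k in names(config$strategies)) {
    for (line in c("first_line", "second_line")) {
      l <- config$strategies[[k]][[line]]
      if (identical(l$regimen, "FOLFIRI")) {
        l$regimen <- "XELIRI"
        l$cost_zar <- xe
        config$strategies[[k]][[line]] <- l
      }
    }
  }
  config
}

# ---- simple figures --------------------------------------------------------

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa A [run_psa()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability_optimal,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (I$/DALY averted)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param tornado A [run_tornado()] result.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  d <- tornado
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "icer_base"),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (I$/DALY averted)", y = NULL) +
    ggplot2::theme_minimal()
}
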